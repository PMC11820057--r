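test_that("epoch RMS matches closed forms", {
  x <- rbind(c(3, 4), c(0, 0), c(-2, -2))
  expect_equal(epoch_rms(x), c(sqrt(12.5), 0, 2))
})

test_that("RMS smoothing has the documented fixed points and edge rule", {
  r <- c(4, 7, 1, 9, 2)
  expect_identical(smooth_rms(r, 0), r)
  expect_equal(smooth_rms(rep(3, 10), 2), rep(3, 10))
  expect_equal(smooth_rms(c(0, 10, 0), 1)[2], sqrt(100 / 3))
  # edges renormalize by the truncated window size
  expect_equal(smooth_rms(c(0, 10, 0), 1)[1], sqrt(50))
  # smoothing is a contraction on the range
  set.seed(1)
  for (w in 1:3) {
    v <- abs(rnorm(50, 5, 3))
    sm <- smooth_rms(v, w)
    expect_lte(max(sm), max(v) + 1e-12)
    expect_gte(min(sm), min(v) - 1e-12)
  }
})

test_that("the RMS mixture recovers planted components and thresholds follow", {
  set.seed(5)
  r <- c(rnorm(500, 1, 0.1), rnorm(500, 10, 0.5))
  g <- fit_rms_gmm(r)
  expect_lt(abs(g$means[1] - 1), 0.1)
  expect_lt(abs(g$means[2] - 10), 0.1)
  expect_equal(sum(g$weights), 1)

  thr <- amplitude_thresholds(g)
  expect_lt(abs(thr$t_low - 0.6), 0.3)
  expect_lt(abs(thr$t_high - 12.0), 0.3)

  expect_error(fit_rms_gmm(rep(2, 100)), "manual")
})

test_that("amplitude thresholds follow the M +/- k*sigma closed form", {
  g <- structure(list(means = c(1, 10), sds = c(0.1, 0.5),
                      weights = c(0.5, 0.5)), class = "gmm_split")
  thr <- amplitude_thresholds(g, k_sd = 4)
  expect_equal(thr$t_low, 0.6)
  expect_equal(thr$t_high, 12.0)
  thr0 <- amplitude_thresholds(g, k_sd = 0)
  expect_equal(c(thr0$t_low, thr0$t_high), c(1, 10))
  # t_low clipped at zero
  g2 <- structure(list(means = c(0.2, 10), sds = c(0.5, 0.5),
                       weights = c(0.5, 0.5)), class = "gmm_split")
  expect_equal(amplitude_thresholds(g2)$t_low, 0)
})

test_that("amplitude flags use strict comparisons and are monotone in k_sd", {
  t <- list(t_low = 1, t_high = 5)
  r <- c(0.5, 1, 3, 5, 6)
  f <- flag_amplitude_artifacts(r, t)
  expect_identical(as.logical(f), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(attr(f, "reason"),
                   c("amplitude", "none", "none", "none", "amplitude"))

  set.seed(2)
  r2 <- c(rnorm(300, 1, 0.1), rnorm(300, 10, 0.5), 0.01, 25)
  g <- fit_rms_gmm(r2)
  flags_by_k <- lapply(c(2, 4, 6), function(k)
    as.logical(flag_amplitude_artifacts(r2, amplitude_thresholds(g, k))))
  expect_true(all(flags_by_k[[2]] <= flags_by_k[[1]]))
  expect_true(all(flags_by_k[[3]] <= flags_by_k[[2]]))
})

test_that("Epanechnikov KDE flags planted outliers and only them", {
  set.seed(11)
  n <- 1000
  cloud <- matrix(rnorm(2 * n), ncol = 2)
  planted <- cbind(c(7, 8.5, 10, 8, 6.5), c(8, 6.5, 9, 10, 6))
  X <- rbind(cloud, planted)
  Xz <- scale(X)

  dens <- somnoscore:::epanechnikov_density(Xz)
  # independent brute-force oracle of the same estimator
  h <- nrow(Xz)^(-1 / 6)
  oracle <- vapply(seq_len(nrow(Xz)), function(i) {
    d2 <- (Xz[i, 1] - Xz[, 1])^2 + (Xz[i, 2] - Xz[, 2])^2
    mean(pmax(0, 1 - d2 / h^2)) * 2 / (pi * h^2)
  }, numeric(1))
  expect_equal(dens, oracle, tolerance = 1e-12)

  flagged <- which(log(dens) < -5)
  expect_identical(flagged, which(log(oracle) < -5))
  # every planted point is flagged; flags among the cloud are confined to
  # its genuinely sparse fringe
  expect_true(all((n + 1:5) %in% flagged))
  expect_lte(sum(flagged <= n) / n, 0.02)
})

test_that("density flagging respects its threshold limit and scaling invariance", {
  sim <- fix_sim24()
  spectra <- fix_spectra24()
  x <- fix_epochs24()
  r_raw <- epoch_rms(x)
  none <- flag_density_artifacts(r_raw, spectra, log_density_threshold = -Inf)
  expect_false(any(none))
  f1 <- flag_density_artifacts(r_raw, spectra)
  f2 <- flag_density_artifacts(r_raw * 7.5, spectra)
  expect_identical(as.logical(f1), as.logical(f2))
  expect_error(flag_density_artifacts(r_raw[1:30], spectra), "50 usable")
})

test_that("artifact masks jointly cover the injected truth on 24-h data", {
  sim <- fix_sim24()
  art <- fix_artifacts24()
  truth <- sim$artifact_mask
  coverage <- sum(art$flags & truth) / sum(truth)
  false_rate <- sum(art$flags & !truth) / sum(!truth)
  expect_gte(coverage, 0.9)
  expect_lte(false_rate, 0.02)
  # overall contamination sits in the low single-digit percent range
  expect_lt(mean(truth), 0.04)
  expect_gt(mean(truth), 0.01)
})

test_that("artifact epochs are restored from the nearest preceding stage", {
  h <- hypnogram(c("W", "ART", "ART", "NR"), 10)
  out <- restore_artifact_epochs(h, h$labels == "ART")
  expect_identical(out$labels, c("W", "W", "W", "NR"))

  h2 <- hypnogram(c("ART", "ART", "R", "W"), 10)
  out2 <- restore_artifact_epochs(h2, h2$labels == "ART")
  expect_identical(out2$labels, c("R", "R", "R", "W"))

  h3 <- hypnogram(c("W", "NR", "R"), 10)
  expect_identical(restore_artifact_epochs(h3, rep(FALSE, 3))$labels,
                   h3$labels)
  expect_error(restore_artifact_epochs(h3, rep(TRUE, 3)), "all epochs")
})
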
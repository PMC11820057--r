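test_that("wake reduction never retains sub-threshold epochs and rejects flat input", {
  set.seed(21)
  r <- c(abs(rnorm(300, 5, 0.8)), abs(rnorm(300, 20, 2)), abs(rnorm(300, 5, 0.8)))
  wr <- reduce_wake(r, epoch_len_s = 10, wide_halfwidth_s = 150)
  expect_true(all(wr$smoothed_wide[wr$retained] > wr$threshold))
  expect_true(all(wr$retained <= wr$retained_threshold))
  expect_error(reduce_wake(rep(3, 500), 10), "manual")
})

test_that("post-crossing removal drops the ascending slope only", {
  r <- c(rep(1, 60), rep(10, 100), rep(1, 60))
  wr <- reduce_wake(r, epoch_len_s = 10, wide_halfwidth_s = 10,
                    post_crossing_remove = 20L, manual_threshold = 5)
  up <- which(wr$retained_threshold & !c(TRUE, head(wr$retained_threshold, -1)))
  expect_length(up, 1)
  expect_true(all(!wr$retained[up:(up + 19)]))
  expect_true(all(wr$retained[(up + 20):max(which(wr$retained_threshold))]))
})

test_that("second-iteration trim keeps REM cores and leaves REM-free segments", {
  # one retained segment spanning epochs 11..30 with REM at 18..22
  retained <- rep(FALSE, 40)
  retained[11:30] <- TRUE
  wr <- structure(list(retained = retained, retained_threshold = retained,
                       threshold = 1, smoothed_wide = rep(2, 40),
                       gmm = NULL, halfwidth_epochs = 1, crossings = integer()),
                  class = "wake_reduction")
  rem <- rep(FALSE, 40); rem[18:22] <- TRUE
  out <- second_iteration_trim(wr, rem)
  expect_identical(which(out$retained), 18:22)

  # no REM: unchanged; and always a subset of the input
  out0 <- second_iteration_trim(wr, rep(FALSE, 40))
  expect_identical(out0$retained, retained)
  expect_true(all(out$retained <= wr$retained))

  # two REM runs in a segment: everything between them is kept
  rem2 <- rep(FALSE, 40); rem2[c(13, 14, 27, 28)] <- TRUE
  out2 <- second_iteration_trim(wr, rem2)
  expect_identical(which(out2$retained), 13:28)
})

test_that("two-step clustering recovers a planted three-cluster structure", {
  set.seed(31)
  n <- c(nrem = 300, wake = 200, rem = 120)
  ds <- c(rnorm(n[1], 20, 1.5), rnorm(n[2], 6, 1), rnorm(n[3], 6, 1))
  theta <- c(rnorm(n[1], 6, 1), rnorm(n[2], 5, 0.8), rnorm(n[3], 14, 1))
  truth <- rep(c(FALSE, FALSE, TRUE), n)
  lab <- bc_classify_rem(theta, ds, seed = 1)
  expect_gte(sum(lab & truth) / sum(truth), 0.95)
  expect_gte(sum(lab & truth) / sum(lab), 0.95)

  # invariant under common positive scaling of both features
  expect_identical(lab, bc_classify_rem(theta * 3, ds * 3, seed = 1))

  # degenerate theta remainder leads to abstention
  ds2 <- c(rnorm(300, 20, 1), rnorm(100, 5, 0.5))
  th2 <- c(rnorm(300, 5, 1), rep(4, 100))
  expect_null(bc_classify_rem(th2, ds2, seed = 1))
})

test_that("stringency voting matches the counting oracle and its tie rule", {
  ones <- rep(TRUE, 6)
  expect_true(all(stringency_vote(list(ones, ones, ones))))
  # strict majority: 3 of 4 is REM, exactly half is not
  half <- stringency_vote(list(c(TRUE, TRUE), c(TRUE, FALSE),
                               c(TRUE, TRUE), c(FALSE, FALSE)))
  expect_identical(as.logical(half), c(TRUE, FALSE))

  set.seed(41)
  votes <- lapply(1:7, function(i) runif(30) < 0.5)
  for (frac in c(0.3, 0.5, 0.8, 1)) {
    got <- as.logical(stringency_vote(votes, frac))
    counts <- Reduce(`+`, votes)
    oracle <- if (frac >= 1) counts >= 7 else counts > frac * 7
    expect_identical(got, oracle)
  }
  # raising stringency never adds REM epochs
  low <- as.logical(stringency_vote(votes, 0.3))
  high <- as.logical(stringency_vote(votes, 0.8))
  expect_true(all(high <= low))

  # abstentions shrink the effective count
  v2 <- c(votes[1:3], list(NULL))
  expect_identical(attr(stringency_vote(v2), "n_effective"), 3L)
  expect_error(stringency_vote(list(NULL, NULL)), "abstained")
})

test_that("the SD ellipse has closed-form geometry and recovers covariance", {
  set.seed(51)
  th <- rnorm(400); ds <- rnorm(400)
  counts <- rep(10, 400)
  e1 <- fit_rem_ellipse(th, ds, counts, magnification = 1)
  expect_equal(unname(e1$center), c(mean(th), mean(ds)))
  expect_equal(e1$covariance, cov(cbind(theta = th, ds = ds)))

  # magnification only scales the acceptance radius
  e15 <- fit_rem_ellipse(th, ds, counts, magnification = 1.5)
  inside1 <- apply_ellipse_correction(rep(FALSE, 400), e1, th, ds)
  inside15 <- apply_ellipse_correction(rep(FALSE, 400), e15, th, ds)
  expect_true(all(inside1 <= inside15))
  d <- sqrt(mahalanobis(cbind(th, ds), e1$center, e1$covariance))
  expect_identical(inside1, d <= 1)
  expect_identical(inside15, d <= 1.5)

  # correlated Gaussian: fitted covariance within 10% elementwise
  set.seed(52)
  z <- matrix(rnorm(2 * 800), ncol = 2) %*% chol(matrix(c(1, .6, .6, 1), 2))
  ec <- fit_rem_ellipse(z[, 1], z[, 2], rep(10, 800))
  expect_true(all(abs(ec$covariance - matrix(c(1, .6, .6, 1), 2)) <= 0.1))

  expect_error(fit_rem_ellipse(th[1:5], ds[1:5], rep(10, 5)), "manual contour")
})

test_that("ellipse correction converts interior points and spares distant ones", {
  e <- structure(list(center = c(0, 0), covariance = diag(2),
                      magnification = 1.5), class = "rem_ellipse")
  lab <- apply_ellipse_correction(c(FALSE, FALSE, TRUE),
                                  e, c(0, 3, 5), c(0, 0, 5))
  expect_identical(lab, c(TRUE, FALSE, TRUE))
})

test_that("polygon contour correction matches the even-odd oracle", {
  square <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  set.seed(61)
  px <- runif(200, -2, 2); py <- runif(200, -2, 2)
  got <- manual_contour_correction(rep(FALSE, 200), square, px, py)
  expect_identical(got, abs(px) < 1 & abs(py) < 1)

  all_in <- manual_contour_correction(rep(FALSE, 200),
                                      100 * square, px, py)
  expect_true(all(all_in))

  # a concave polygon against a brute-force even-odd oracle
  poly <- rbind(c(0, 0), c(4, 0), c(4, 4), c(2, 1.5), c(0, 4))
  got2 <- manual_contour_correction(rep(FALSE, 200), poly,
                                    px + 2, py + 2)
  oracle <- vapply(seq_along(px), function(i) {
    x <- px[i] + 2; y <- py[i] + 2
    inside <- FALSE
    j <- nrow(poly)
    for (k in seq_len(nrow(poly))) {
      if ((poly[k, 2] > y) != (poly[j, 2] > y) &&
          x < (poly[j, 1] - poly[k, 1]) * (y - poly[k, 2]) /
            (poly[j, 2] - poly[k, 2]) + poly[k, 1]) inside <- !inside
      j <- k
    }
    inside
  }, logical(1))
  expect_identical(got2, oracle)

  expect_error(manual_contour_correction(rep(FALSE, 2), square[1:2, ],
                                         c(0, 0), c(0, 0)), "3 vertices")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(manual_contour_correction(rep(FALSE, 2), bowtie,
                                         c(0, 0), c(0, 0)),
               "self-intersecting")
})
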
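test_that("generated hypnograms honor the configured stage structure", {
  h <- fix_sim24()$hypnogram
  fr <- table(factor(h$labels, levels = c("W", "NR", "R"))) / length(h$labels)
  expect_lt(abs(fr[["W"]] - 0.45), 0.05)
  expect_lt(abs(fr[["NR"]] - 0.45), 0.05)
  expect_lt(abs(fr[["R"]] - 0.10), 0.05)

  # REM never follows wake, across several seeds and durations
  for (s in 1:4) {
    hh <- generate_hypnogram(sim_config(duration_s = 6 * 3600, seed = s))
    runs <- rle(hh$labels)
    ri <- which(runs$values == "R")
    expect_true(all(ri > 1))
    expect_true(all(runs$values[ri - 1] == "NR"))
  }
})

test_that("degenerate configurations behave as documented", {
  cfg0 <- sim_config(duration_s = 6 * 3600, seed = 3,
                     stage_fractions = c(W = 0.5, NR = 0.5, R = 0))
  expect_false("R" %in% generate_hypnogram(cfg0)$labels)
  expect_error(sim_config(duration_s = 5), "shorter than one epoch")
  expect_error(sim_config(stage_fractions = c(W = 0.6, NR = 0.6, R = 0.1)),
               "sum to 1")
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(duration_s = 1800, seed = 17)
  a <- simulate_psg(cfg)
  b <- simulate_psg(cfg)
  expect_identical(a$hypnogram$labels, b$hypnogram$labels)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$artifact_mask, b$artifact_mask)
})

test_that("synthesized EEG has the stage-dependent amplitude structure", {
  cfg <- sim_config(duration_s = 3600, seed = 7,
                    artifact_rates = c(high_amp_per_hour = 0,
                                       flatline_per_hour = 0,
                                       normal_amp_per_hour = 0))
  sim <- simulate_psg(cfg)
  x <- epoch_signal(sim$recording, 10)
  r <- epoch_rms(x)
  lab <- sim$hypnogram$labels
  expect_gt(mean(r[lab == "NR"]), mean(r[lab == "W"]))
  expect_gt(mean(r[lab == "NR"]), mean(r[lab == "R"]))

  s <- epoch_spectra(x)
  delta <- extract_band(s, band(2, 4), summed = TRUE)
  theta <- extract_band(s, band(5, 10), summed = TRUE)
  # REM: theta dominates delta; spectral separation across stages
  expect_gt(mean(theta[lab == "R"]), mean(delta[lab == "R"]))
  expect_gt(mean(delta[lab == "NR"]), mean(delta[lab == "W"]))
  expect_gt(mean(delta[lab == "NR"]), mean(delta[lab == "R"]))
  expect_gt(mean(theta[lab == "R"]), mean(theta[lab == "W"]))
})

test_that("an all-NREM hypnogram yields delta-dominated spectra", {
  cfg <- sim_config(duration_s = 600, seed = 2)
  h <- hypnogram(rep("NR", 60), 10)
  rec <- synthesize_eeg(h, cfg)
  s <- epoch_spectra(epoch_signal(rec, 10))
  expect_gt(mean(extract_band(s, band(1, 4), summed = TRUE)),
            mean(extract_band(s, band(5, 10), summed = TRUE)))
})

test_that("artifact injection matches its ground-truth mask", {
  cfg0 <- sim_config(duration_s = 3600, seed = 9,
                     artifact_rates = c(high_amp_per_hour = 0,
                                        flatline_per_hour = 0,
                                        normal_amp_per_hour = 0))
  h <- generate_hypnogram(cfg0)
  rec <- synthesize_eeg(h, cfg0)
  gt <- inject_artifacts(rec, h, cfg0)
  expect_false(any(gt$artifact_mask))
  expect_identical(gt$recording$samples, rec$samples)

  # flatline epochs collapse to < 1% of the median epoch RMS
  cfg1 <- sim_config(duration_s = 6 * 3600, seed = 9,
                     artifact_rates = c(high_amp_per_hour = 0,
                                        flatline_per_hour = 1,
                                        normal_amp_per_hour = 0))
  gt1 <- simulate_psg(cfg1)
  r <- epoch_rms(epoch_signal(gt1$recording, 10))
  flat <- gt1$artifact_type == "flatline"
  expect_gt(sum(flat), 0)
  expect_true(all(r[flat] < 0.01 * median(r)))
})

test_that("injected high-amplitude epochs are recoverable by thresholding", {
  sim <- fix_sim24()
  art <- fix_artifacts24()
  high <- which(sim$artifact_type == "high_amp")
  expect_true(all(art$flags[high]))
  expect_gte(mean(art$reason[high] == "amplitude"), 0.9)
})
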
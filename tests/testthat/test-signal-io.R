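test_that("csv recordings load with an explicit sampling rate", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(as.character(sin(seq_len(1040))), f)
  rec <- load_recording(f, "csv", fs_override = 104)
  expect_length(rec$samples, 1040)
  expect_equal(rec$fs, 104)
  expect_error(load_recording(f, "csv"), "fs_override")
  expect_error(load_recording("no-such-file.csv", "csv", fs_override = 10),
               "not found")
})

test_that("EDF files round-trip within quantization error", {
  f <- withr::local_tempfile(fileext = ".edf")
  x <- sin(2 * pi * 3 * seq_len(104 * 20) / 104) * 50
  write_edf(x, fs = 104, path = f)
  rec <- load_recording(f, "edf")
  expect_length(rec$samples, length(x))
  expect_equal(rec$fs, 104)
  expect_lt(max(abs(rec$samples - x)), diff(range(x)) / 65000 * 2)
})

test_that("named EDF channels are selected and absent names rejected", {
  f <- withr::local_tempfile(fileext = ".edf")
  sig <- list(EEG1 = rnorm(1040), EEG2 = 10 + rnorm(1040))
  write_edf(sig, fs = 104, path = f)
  rec <- load_recording(f, "edf", channel = "EEG2")
  expect_equal(rec$channel, "EEG2")
  expect_gt(mean(rec$samples), 5)
  rec1 <- load_recording(f, "edf")
  expect_equal(rec1$channel, "EEG1")
  expect_error(load_recording(f, "edf", channel = "EMG"), "not present")
})

test_that("sampling-rate regularization rounds to integer and is idempotent", {
  rec <- sine_recording(5, fs = 104, dur_s = 30)
  expect_identical(regularize_fs(rec)$samples, rec$samples)

  t <- seq_len(round(103.6 * 60)) / 103.6
  rec2 <- eeg_recording(sin(2 * pi * 5 * t), fs = 103.6)
  out <- regularize_fs(rec2)
  expect_equal(out$fs, 104)
  expect_equal(length(out$samples), round(length(rec2$samples) * 104 / 103.6))
  # spectral peak stays at 5 Hz within one bin
  s <- epoch_spectra(epoch_signal(out, 10))
  peak <- s$freqs[which.max(colMeans(s$amplitudes[, -1])) + 1]
  expect_lt(abs(peak - 5), 104 / 256)
  expect_identical(regularize_fs(out)$samples, out$samples)
})

test_that("high-pass filter rejects DC, keeps the passband, and is linear", {
  fs <- 104
  const <- eeg_recording(rep(5, fs * 30), fs)
  yc <- highpass_eeg(const)$samples
  inner <- seq(fs * 8, length(yc) - fs * 8) # steady state, past transients
  expect_lt(max(abs(yc[inner])), 5e-6 * 5)

  s8 <- sine_recording(8, dur_s = 30)
  y8 <- highpass_eeg(s8)
  mid <- seq(fs * 5, fs * 25)
  expect_lt(abs(sd(y8$samples[mid]) / sd(s8$samples[mid]) - 1), 0.05)

  mix <- eeg_recording(sine_recording(0.5, dur_s = 40)$samples +
                         sine_recording(8, dur_s = 40)$samples, fs)
  ym <- highpass_eeg(mix)
  sp <- epoch_spectra(epoch_signal(ym, 10))
  sp0 <- epoch_spectra(epoch_signal(mix, 10))
  b_low <- which(sp$freqs > 0.2 & sp$freqs < 0.9)
  b_8 <- which(abs(sp$freqs - 8) < 0.5)
  att_low <- sum(sp$amplitudes[, b_low]) / sum(sp0$amplitudes[, b_low])
  expect_lt(20 * log10(att_low), -20)
  expect_lt(abs(sum(sp$amplitudes[, b_8]) / sum(sp0$amplitudes[, b_8]) - 1),
            0.05)

  # linearity
  a <- sine_recording(4, dur_s = 20)$samples
  b <- sine_recording(9, dur_s = 20)$samples
  lhs <- highpass_eeg(eeg_recording(2 * a + 3 * b, fs))$samples
  rhs <- 2 * highpass_eeg(eeg_recording(a, fs))$samples +
    3 * highpass_eeg(eeg_recording(b, fs))$samples
  expect_lt(max(abs(lhs - rhs)), 1e-8)

  expect_error(highpass_eeg(const, cutoff = 60), "Nyquist")
})

test_that("epoching partitions the signal exactly", {
  rec <- eeg_recording(rnorm(25000), fs = 100)
  x <- epoch_signal(rec, 10)
  expect_equal(dim(x), c(25, 1000))
  expect_identical(as.numeric(t(x)), rec$samples)

  rec2 <- eeg_recording(rnorm(25050), fs = 100)
  x2 <- epoch_signal(rec2, 10)
  expect_equal(nrow(x2), 25)
  expect_identical(as.numeric(t(x2)), rec2$samples[1:25000])

  expect_error(epoch_signal(eeg_recording(rnorm(500), 100), 10),
               "shorter than one epoch")
})

test_that("hypnogram files round-trip and reject unknown tokens", {
  h <- hypnogram(c("W", "NR", "R", "ART", "W"), 10)
  f <- withr::local_tempfile(fileext = ".txt")
  write_hypnogram(h, f)
  expect_identical(read_hypnogram(f, 10)$labels, h$labels)

  writeLines(c("W", "NR", "X", "R"), f)
  expect_error(read_hypnogram(f), "line 3")
  expect_error(hypnogram(c("W", "REM")), "unknown stage token")
})
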
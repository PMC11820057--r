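# Shared fixtures, computed lazily and memoized so the expensive 24-h
# simulation and full pipeline run once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# 24-h default-configuration synthetic recording, seed 1
fix_sim24 <- function() memo("sim24", simulate_psg(sim_config(seed = 1)))

fix_epochs24 <- function() memo("epochs24",
  epoch_signal(fix_sim24()$recording, 10))

fix_spectra24 <- function() memo("spectra24", epoch_spectra(fix_epochs24()))

fix_artifacts24 <- function() memo("artifacts24",
  detect_artifacts(fix_epochs24(), fix_spectra24()))

# full two-iteration rat-default pipeline fit on the same recording
fix_fit24 <- function() memo("fit24",
  score_psg(fix_sim24()$recording, score_config("rat")))

# small artifact-free simulation for cheap structural tests
fix_sim_small <- function() memo("sim_small",
  simulate_psg(sim_config(duration_s = 2 * 3600, seed = 5,
                          artifact_rates = c(high_amp_per_hour = 0,
                                             flatline_per_hour = 0,
                                             normal_amp_per_hour = 0))))

# sine-wave recording helper
sine_recording <- function(freq, fs = 104, dur_s = 60, amp = 1) {
  t <- seq_len(fs * dur_s) / fs
  eeg_recording(amp * sin(2 * pi * freq * t), fs = fs)
}
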
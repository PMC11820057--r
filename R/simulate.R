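#' Configuration for the synthetic polysomnography generator
#'
#' The generator emulates the statistical structure of a 24-h rodent
#' single-EEG recording: a 12:12 light/dark cycle with sleep-dominant light
#' and wake-dominant dark phases; consolidated wake episodes alternating
#' with sleep phases made of NREM bouts, brief arousals and REM bouts that
#' always follow sustained NREM; stage-dependent spectra (NREM:
#' high-amplitude 1-4 Hz delta plus 11-16 Hz spindle bursts; REM: dominant
#' 5-10 Hz theta at low overall amplitude; wake: low-amplitude activity with
#' modest theta); and seeded artifact injection.
#'
#' @param duration_s recording length in seconds (default 24 h).
#' @param fs sampling rate, Hz (default 104).
#' @param epoch_len_s epoch length, seconds (default 10).
#' @param seed integer seed; the full output is reproducible given the
#'   configuration.
#' @param stage_fractions named fractions for `W`, `NR`, `R` summing to 1.
#' @param bout_mean_epochs named mean bout lengths in epochs: `W` is the
#'   consolidated (inter-sleep) wake episode scale reference, `NR` and `R`
#'   the NREM/REM bout means.
#' @param light_wake_fraction wake fraction of the light (rest) phase; the
#'   dark-phase fraction is derived so the 24-h average matches
#'   `stage_fractions["W"]`.
#' @param sleep_phase_mean_cycles mean number of NREM(-REM) cycles per
#'   consolidated sleep phase, named for `light` and `dark`.
#' @param brief_wake_prob,brief_wake_mean_epochs probability and mean length
#'   of brief arousals between sleep cycles.
#' @param min_nrem_before_rem minimum NREM bout length (epochs) before a
#'   transition into REM (REM latency after sleep onset).
#' @param spectral_params per-stage synthesis parameters; see Details.
#' @param amplitude_drift slow multiplicative RMS drift shared by all
#'   components: `list(sd=, tau_epochs=)`, a lognormal AR(1) factor
#'   emulating behavioral amplitude variability (default 13\% with a
#'   ~200-s correlation time).
#' @param artifact_rates events per hour:
#'   `high_amp_per_hour`, `flatline_per_hour`, `normal_amp_per_hour`.
#' @param light_first does the recording start in the light phase?
#'
#' @details `spectral_params` is a list with per-stage amplitude entries
#' (`W`, `NR`, `R`, each with `noise_rms`, `delta_amp`, `theta_amp`,
#' `sigma_amp`; sine amplitudes in the same units as `noise_rms`) and the
#' oscillator centers `delta_hz`, `theta_hz`, `sigma_hz`. Defaults give
#' mean epoch RMS of roughly 22 (wake), 47 (NREM) and 33 (REM) units.
#'
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 86400,
                       fs = 104,
                       epoch_len_s = 10,
                       seed = 1L,
                       stage_fractions = c(W = 0.45, NR = 0.45, R = 0.10),
                       bout_mean_epochs = c(W = 18, NR = 18, R = 6),
                       light_wake_fraction = 0.25,
                       sleep_phase_mean_cycles = c(light = 20, dark = 8),
                       brief_wake_prob = 0.5,
                       brief_wake_mean_epochs = 1.5,
                       min_nrem_before_rem = 12,
                       spectral_params = default_spectral_params(),
                       amplitude_drift = list(sd = 0.13, tau_epochs = 20),
                       artifact_rates = c(high_amp_per_hour = 2,
                                          flatline_per_hour = 0.4,
                                          normal_amp_per_hour = 2),
                       light_first = TRUE) {
  if (duration_s < epoch_len_s) stop("duration shorter than one epoch")
  if (fs <= 0 || epoch_len_s <= 0) stop("fs and epoch_len_s must be positive")
  spe <- fs * epoch_len_s
  if (abs(spe - round(spe)) > 1e-9)
    stop("fs * epoch_len_s must be an integer")
  sf <- stage_fractions[c("W", "NR", "R")]
  if (anyNA(sf) || any(sf < 0) || abs(sum(sf) - 1) > 1e-8)
    stop("stage_fractions must be nonnegative and sum to 1 over W, NR, R")
  if (any(artifact_rates < 0)) stop("artifact rates must be >= 0")
  dark_wake <- 2 * sf[["W"]] - light_wake_fraction
  if (dark_wake < 0 || dark_wake > 1)
    stop("light_wake_fraction incompatible with stage_fractions['W']")
  structure(list(
    duration_s = duration_s, fs = fs, epoch_len_s = epoch_len_s,
    seed = as.integer(seed),
    stage_fractions = sf,
    bout_mean_epochs = bout_mean_epochs,
    light_wake_fraction = light_wake_fraction,
    dark_wake_fraction = dark_wake,
    sleep_phase_mean_cycles = sleep_phase_mean_cycles,
    brief_wake_prob = brief_wake_prob,
    brief_wake_mean_epochs = brief_wake_mean_epochs,
    min_nrem_before_rem = min_nrem_before_rem,
    spectral_params = spectral_params,
    amplitude_drift = amplitude_drift,
    artifact_rates = artifact_rates,
    light_first = light_first,
    # recordings shorter than a day span one light and one dark phase of
    # equal length, so realized fractions track stage_fractions regardless
    # of duration
    period_s = min(43200, duration_s / 2)), class = "sim_config")
}

#' Default per-stage spectral synthesis parameters
#' @return List used by [sim_config()]; see its Details section.
#' @export
default_spectral_params <- function() {
  list(
    W = list(noise_rms = 20, delta_amp = 5, theta_amp = 12, sigma_amp = 0),
    NR = list(noise_rms = 25, delta_amp = 55, theta_amp = 5, sigma_amp = 25),
    R = list(noise_rms = 13, delta_amp = 5, theta_amp = 42, sigma_amp = 0),
    delta_hz = 2.5, theta_hz = 7, sigma_hz = 13)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic PSG config: %.1f h at %g Hz, %g-s epochs, seed %d\n",
              x$duration_s / 3600, x$fs, x$epoch_len_s, x$seed))
  cat(sprintf("  stage fractions W/NR/R: %.2f/%.2f/%.2f; wake fraction %.2f (light) / %.2f (dark)\n",
              x$stage_fractions[1], x$stage_fractions[2], x$stage_fractions[3],
              x$light_wake_fraction, x$dark_wake_fraction))
  invisible(x)
}

# Truncated geometric bout length: support >= minimum, mean approximately
# `mean_len`, capped at 3x the mean to bound single-bout variance.
rtgeom <- function(n, mean_len, minimum = 1) {
  excess <- max(mean_len - minimum, 1e-9)
  x <- minimum + rgeom(n, prob = 1 / (1 + excess))
  pmin(x, ceiling(3 * mean_len))
}

#' Generate a ground-truth hypnogram
#'
#' Semi-Markov bout construction: consolidated wake episodes alternate with
#' sleep phases of geometric cycle counts; each cycle is a NREM bout
#' (minimum length before REM entry), an optional REM bout, and an optional
#' brief arousal. REM entry probability is derived from the configured stage
#' fractions and bout means, and every REM bout directly follows NREM by
#' construction. The generator never emits `ART` labels.
#'
#' @param config a [sim_config()].
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_ep <- floor(config$duration_s / config$epoch_len_s)
  if (n_ep < 1L) stop("duration shorter than one epoch")
  with_seed(config$seed, .generate_hypnogram_impl(config, n_ep))
}

.generate_hypnogram_impl <- function(config, n_ep) {
  sf <- config$stage_fractions
  L_N <- config$bout_mean_epochs[["NR"]]
  L_R <- config$bout_mean_epochs[["R"]]
  # REM entry probability after a NREM bout, from the target NR:R balance
  p_rem <- if (sf[["R"]] <= 0 || sf[["NR"]] <= 0) 0 else
    min(1, (sf[["R"]] / sf[["NR"]]) * (L_N / L_R))
  sleep_per_cycle <- L_N + p_rem * L_R
  brief_mean <- config$brief_wake_prob * config$brief_wake_mean_epochs
  ep_per_phase <- config$period_s / config$epoch_len_s
  wake_frac <- c(light = config$light_wake_fraction,
                 dark = config$dark_wake_fraction)
  phase_of <- function(pos) { # pos is 0-based epoch index
    half <- (pos %/% ep_per_phase) %% 2
    if (config$light_first) c("light", "dark")[half + 1]
    else c("dark", "light")[half + 1]
  }
  labels <- character(n_ep)
  pos <- 0L
  # running totals for the drift control below; per-phase REM share
  r_share <- if (sleep_per_cycle > 0) p_rem * L_R / sleep_per_cycle else 0
  got_w <- 0; got_r <- 0; want_w <- 0; want_r <- 0
  emit <- function(stage, len) {
    len <- min(len, n_ep - pos)
    if (len > 0L) {
      labels[pos + seq_len(len)] <<- stage
      if (stage == "W") got_w <<- got_w + len
      if (stage == "R") got_r <<- got_r + len
      fw_here <- wake_frac[[phase_of(pos)]]
      want_w <<- want_w + len * fw_here
      want_r <<- want_r + len * (1 - fw_here) * r_share
    }
    pos <<- pos + as.integer(len)
  }
  while (pos < n_ep) {
    ph <- phase_of(pos)
    m <- config$sleep_phase_mean_cycles[[ph]]
    fw <- wake_frac[[ph]]
    fsleep <- max(1 - fw, 1e-9)
    long_wake_mean <- max(1, m * sleep_per_cycle * fw / fsleep -
                            brief_mean * (m - 1))
    if (fw >= 1 - 1e-9) { # degenerate: all-wake phase
      emit("W", ep_per_phase)
      next
    }
    # bout lengths stay geometric, but the mean of the next consolidated
    # wake bout absorbs part of the realized-vs-target wake drift so that
    # long recordings settle near the configured stage fractions
    adj <- max(0.25 * long_wake_mean,
               min(2.5 * long_wake_mean, long_wake_mean + 0.9 * (want_w - got_w)))
    emit("W", rtgeom(1, adj))
    # symmetric control: a wake surplus lengthens the following sleep phase
    m_adj <- max(0.3 * m, min(2.5 * m,
                              m + 0.9 * (got_w - want_w) / sleep_per_cycle))
    n_cycles <- rtgeom(1, m_adj)
    for (cy in seq_len(n_cycles)) {
      if (pos >= n_ep) break
      if (cy > 1L && runif(1) < config$brief_wake_prob)
        emit("W", rtgeom(1, config$brief_wake_mean_epochs))
      p_adj <- if (p_rem <= 0) 0 else
        max(0.15 * p_rem, min(1, p_rem + 0.8 * (want_r - got_r) / (L_R * 3)))
      if (runif(1) < p_adj) {
        emit("NR", rtgeom(1, L_N, minimum = config$min_nrem_before_rem))
        emit("R", rtgeom(1, L_R))
      } else {
        emit("NR", rtgeom(1, L_N))
      }
    }
  }
  hypnogram(labels, epoch_len_s = config$epoch_len_s)
}

# Per-sample envelope from per-epoch values: piecewise constant with a
# short (~2 s) blend at epoch boundaries, since rodent state transitions
# complete within seconds. Running mean via cumulative sums, O(n).
.epoch_envelope <- function(vals, spe, n_samp, blend_samples = NULL) {
  env <- rep(vals, each = spe)[seq_len(n_samp)]
  w <- blend_samples %||% max(1L, round(spe / 5))
  if (w <= 1L) return(env)
  cs <- cumsum(c(0, env))
  n <- length(env)
  lo <- pmax(seq_len(n) - w, 0L)
  hi <- pmin(seq_len(n) + w, n)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Band-limited white noise (FFT brick-wall), unit RMS.
.bandlimited_noise <- function(n, fs, lo, hi) {
  W <- fft(rnorm(n))
  f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * fs / n
  W[f < lo | f > hi] <- 0
  x <- Re(fft(W, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# 1/f-shaped broadband noise, unit RMS.
.pink_noise <- function(n, fs, f_knee = 1) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * fs / n
  g <- 1 / sqrt(pmax(f, f_knee))
  x <- Re(fft(W * g, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Synthesize stage-conditional EEG for a hypnogram
#'
#' Each stage contributes narrowband oscillators (delta, theta, and
#' burst-modulated sigma spindles) with slowly drifting frequency and
#' amplitude, plus 1/f broadband noise; amplitudes ramp over ~2 epochs at
#' NREM onsets (and offsets into wake), so the wide-window RMS smoothing of
#' the wake-reduction step sees gradual transitions. Deterministic given the
#' configuration seed.
#'
#' @param hyp a ground-truth [hypnogram()] (no `ART` labels).
#' @param config the [sim_config()] that produced it.
#' @return An [eeg_recording()].
#' @export
synthesize_eeg <- function(hyp, config) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(config, "sim_config"))
  with_seed(config$seed + 1L, .synthesize_eeg_impl(hyp, config))
}

.synthesize_eeg_impl <- function(hyp, config) {
  sp <- config$spectral_params
  fs <- config$fs
  spe <- round(fs * config$epoch_len_s)
  lab <- hyp$labels
  n_ep <- length(lab)
  n <- n_ep * spe

  par_names <- c("noise_rms", "delta_amp", "theta_amp", "sigma_amp")
  P <- t(vapply(lab, function(s) unlist(sp[[s]][par_names]), numeric(4)))
  colnames(P) <- par_names

  # 2-epoch amplitude ramps at NREM onset; also at NREM->wake offsets
  runs <- stage_runs(lab)
  for (k in which(runs$stage == "NR")) {
    st <- runs$start[k]; len <- runs$length[k]; en <- st + len - 1L
    if (st > 1L && len >= 2L) {
      prev <- P[st - 1L, ]
      P[st, ] <- 0.45 * P[st, ] + 0.55 * prev
      if (len >= 3L) P[st + 1L, ] <- 0.8 * P[st + 1L, ] + 0.2 * prev
    }
    nxt_is_w <- en < n_ep && lab[en + 1L] == "W"
    if (nxt_is_w && len >= 3L) {
      nxt <- P[en + 1L, ]
      P[en, ] <- 0.45 * P[en, ] + 0.55 * nxt
      if (len >= 4L) P[en - 1L, ] <- 0.8 * P[en - 1L, ] + 0.2 * nxt
    }
  }

  # slow lognormal amplitude drift: real per-epoch RMS varies by 10-20%
  # within a state with minute-scale correlation; without it the smoothed
  # RMS regimes are implausibly flat
  dr <- config$amplitude_drift
  if (!is.null(dr) && dr$sd > 0) {
    a <- exp(-1 / dr$tau_epochs)
    z <- as.numeric(stats::filter(rnorm(n_ep) * sqrt(1 - a^2), a,
                                  method = "recursive"))
    P <- P * exp(dr$sd * z)
  }

  osc <- function(center_hz, jitter_sd, lo, hi, amp_col) {
    f_ep <- pmin(pmax(rnorm(n_ep, center_hz, jitter_sd), lo), hi)
    f_inst <- .epoch_envelope(f_ep, spe, n)
    phase <- cumsum(2 * pi * f_inst / fs) + runif(1, 0, 2 * pi)
    env <- .epoch_envelope(P[, amp_col], spe, n)
    am <- 1 + 0.25 * sin(2 * pi * (seq_len(n) / fs) / runif(1, 13, 23) +
                           runif(1, 0, 2 * pi))
    env * am * sin(phase)
  }
  x <- osc(sp$delta_hz, 0.3, 1.2, 3.8, "delta_amp") +
    osc(sp$theta_hz, 0.4, 5.5, 9.2, "theta_amp")
  # sigma spindles: ~0.7-s bursts recurring every few seconds
  t_s <- seq_len(n) / fs
  burst <- pmax(0, sin(2 * pi * t_s / 4.3 + runif(1, 0, 2 * pi)))^4
  x <- x + burst * osc(sp$sigma_hz, 0.5, 11.5, 15.5, "sigma_amp")
  x <- x + .epoch_envelope(P[, "noise_rms"], spe, n) * .pink_noise(n, fs)
  eeg_recording(x, fs = fs, channel = "EEG",
                start_time = as.POSIXct("2000-01-01 08:00:00", tz = "UTC"))
}

#' Inject artifacts and return the ground truth bundle
#'
#' Three artifact classes are inserted at configured hourly rates:
#' high-amplitude movement-like transients (a 2-4 s burst an order of
#' magnitude above the signal scale); flatline dropouts (6-12 consecutive
#' near-zero epochs, emulating electrode disconnections); and
#' normal-amplitude artifacts of two kinds — muscle-like events (the epoch
#' dominated by 35-50 Hz activity, which keeps the RMS in the normal range
#' but collapses the 2-10 Hz spectral sum) and chewing/scratching-like
#' events (a strong 3-12 Hz rhythm inflating the 2-10 Hz sum at a normal
#' RMS) — with randomized amplitude factors so events scatter in the
#' (RMS, band-sum) feature space as real heterogeneous artifacts do. Most
#' events are placed in wake epochs, where movement artifacts occur in
#' practice.
#'
#' @param rec clean [eeg_recording()] from [synthesize_eeg()].
#' @param hyp the matching ground-truth [hypnogram()].
#' @param config the [sim_config()].
#' @return A `psg_truth` list: `recording` (contaminated), `hypnogram`,
#'   `artifact_mask` (logical per epoch), `artifact_type` (character per
#'   epoch) and `config`.
#' @export
inject_artifacts <- function(rec, hyp, config) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(hyp, "hypnogram"))
  with_seed(config$seed + 2L, .inject_artifacts_impl(rec, hyp, config))
}

.inject_artifacts_impl <- function(rec, hyp, config) {
  fs <- rec$fs
  spe <- round(fs * config$epoch_len_s)
  n_ep <- length(hyp$labels)
  hours <- n_ep * config$epoch_len_s / 3600
  rates <- config$artifact_rates
  n_high <- round(rates[["high_amp_per_hour"]] * hours)
  n_flat <- round(rates[["flatline_per_hour"]] * hours)
  n_norm <- round(rates[["normal_amp_per_hour"]] * hours)

  x <- rec$samples
  mask <- rep(FALSE, n_ep)
  type <- rep("none", n_ep)
  taken <- rep(FALSE, n_ep)
  wake <- hyp$labels == "W"

  pick <- function(n, wake_share = 0.75, span = 1L) {
    if (n == 0L) return(integer(0))
    out <- integer(0)
    for (i in seq_len(n)) {
      pool_w <- which(wake & !taken)
      pool_o <- which(!wake & !taken)
      use_wake <- (runif(1) < wake_share && length(pool_w) >= span) ||
        length(pool_o) < span
      pool <- if (use_wake) pool_w else pool_o
      pool <- pool[pool <= n_ep - span + 1L]
      if (length(pool) == 0L) break
      e <- pool[sample.int(length(pool), 1L)]
      idx <- e:(e + span - 1L)
      if (any(taken[idx])) next
      taken[idx] <<- TRUE
      out <- c(out, e)
    }
    out
  }

  scale_ref <- median(sqrt(colMeans(matrix(x[seq_len(min(length(x),
                                                         n_ep * spe))],
                                           nrow = spe)^2)))

  for (e in pick(n_high, wake_share = 0.75)) {
    dur <- sample(seq(2 * fs, 4 * fs), 1L)
    off <- sample.int(spe - dur, 1L)
    s <- (e - 1L) * spe + off
    x[s:(s + dur - 1L)] <- x[s:(s + dur - 1L)] +
      10 * scale_ref * rnorm(dur)
    mask[e] <- TRUE; type[e] <- "high_amp"
  }
  for (e in pick(n_flat, wake_share = 0.75, span = 13L)) {
    # the dropout starts at an arbitrary sample, so the boundary epochs are
    # only partially attenuated; the truth mask marks fully-flat epochs
    dur <- sample(6:12, 1L)
    off <- sample.int(spe, 1L)
    s0 <- (e - 1L) * spe + off
    idx <- s0:min(s0 + dur * spe - 1L, length(x))
    x[idx] <- x[idx] * 0.002
    full <- which(vapply(seq_len(n_ep), function(k) {
      a <- (k - 1L) * spe + 1L
      a >= idx[1] && (a + spe - 1L) <= idx[length(idx)]
    }, logical(1)))
    mask[full] <- TRUE; type[full] <- "flatline"
  }
  for (e in pick(n_norm, wake_share = 0.6)) {
    idx <- ((e - 1L) * spe + 1L):(e * spe)
    rms0 <- sqrt(mean(x[idx]^2))
    tt <- seq_along(idx) / fs
    if (runif(1) < 0.5) {
      # muscle-like: strong high-frequency power raises the epoch RMS
      # (still well below the 4-SD bound) while the 2-10 Hz sum stays at
      # the baseline floor - a point to the right of the cloud diagonal
      fac <- runif(1, 1.25, 2.2)
      leak <- runif(1, 0, 0.25)
      hf <- sin(2 * pi * (35 + 15 * runif(1)) * tt + runif(1, 0, 2 * pi)) +
        0.3 * rnorm(length(idx))
      art <- hf / sqrt(mean(hf^2)) * sqrt(1 - leak^2) + leak * x[idx] / rms0
    } else {
      # scratching/grooming-like slow broadband burst: band-limited
      # 2-10 Hz noise concentrates the epoch's power in-band, inflating
      # the 2-10 Hz amplitude sum above what its RMS predicts
      fac <- runif(1, 0.95, 1.7)
      blo <- runif(1, 2, 5)
      art <- .bandlimited_noise(length(idx), fs, blo,
                                min(10, blo + runif(1, 3, 8)))
    }
    x[idx] <- art * rms0 * fac
    mask[e] <- TRUE; type[e] <- "normal_amp"
  }

  rec$samples <- x
  structure(list(recording = rec, hypnogram = hyp, artifact_mask = mask,
                 artifact_type = type, config = config),
            class = "psg_truth")
}

#' Simulate a complete synthetic polysomnography recording
#'
#' Runs [generate_hypnogram()], [synthesize_eeg()] and [inject_artifacts()]
#' under the configuration seed.
#'
#' @param config a [sim_config()].
#' @return A `psg_truth` bundle (see [inject_artifacts()]).
#' @examples
#' sim <- simulate_psg(sim_config(duration_s = 3600, seed = 7,
#'                                artifact_rates = c(high_amp_per_hour = 0,
#'                                                   flatline_per_hour = 0,
#'                                                   normal_amp_per_hour = 0)))
#' print(sim$hypnogram)
#' @export
simulate_psg <- function(config = sim_config()) {
  hyp <- generate_hypnogram(config)
  rec <- synthesize_eeg(hyp, config)
  inject_artifacts(rec, hyp, config)
}

#' @export
print.psg_truth <- function(x, ...) {
  cat("Synthetic PSG recording\n")
  print(x$recording)
  print(x$hypnogram)
  cat(sprintf("  artifact epochs: %d (%.1f%%)\n", sum(x$artifact_mask),
              100 * mean(x$artifact_mask)))
  invisible(x)
}
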
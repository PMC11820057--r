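#' Fit the artifact GMM on a smoothed RMS series
#'
#' A 2-component Gaussian mixture on the (20-s smoothed) per-epoch RMS
#' separates the low-amplitude and high-amplitude regimes of the recording;
#' both tails can harbor artifacts (signal dropouts below, movement
#' artifacts above).
#'
#' The mixture is fitted on the central mass of the series (the lowest and
#' highest 2\% of values are set aside) so that rare extreme artifacts
#' cannot capture a component of their own; the resulting thresholds are
#' then applied to every epoch.
#'
#' @param r smoothed per-epoch RMS (see [smooth_rms()]).
#' @param seed initialization seed.
#' @param trim fraction trimmed from each tail before fitting (default 0.02).
#' @return A `gmm_split` (components sorted by mean), with `assignments`
#'   and `posterior_high` covering the full series.
#' @export
fit_rms_gmm <- function(r, seed = 42L, trim = 0.02) {
  q <- quantile(r, c(trim, 1 - trim), names = FALSE)
  core <- r[r >= q[1] & r <= q[2]]
  g <- fit_gmm_1d(core, seed = seed, min_n = 20L)
  # extend assignments to the full series from the fitted parameters
  ll <- vapply(1:2, function(k)
    log(g$weights[k]) + dnorm(r, g$means[k], g$sds[k], log = TRUE),
    numeric(length(r)))
  g$assignments <- as.integer(ll[, 2] > ll[, 1]) + 1L
  g$posterior_high <- 1 / (1 + exp(ll[, 1] - ll[, 2]))
  g
}

#' Amplitude artifact thresholds from a fitted RMS mixture
#'
#' `t_high = M_high + k_sd * sigma_high`, `t_low = M_low - k_sd * sigma_low`,
#' with `t_low` clipped at 0 (RMS is nonnegative).
#'
#' @param g a `gmm_split` from [fit_rms_gmm()].
#' @param k_sd tail width in component standard deviations (default 4).
#' @return List with `t_low`, `t_high`, `source = "automatic"`.
#' @export
amplitude_thresholds <- function(g, k_sd = 4) {
  stopifnot(inherits(g, "gmm_split"))
  t_high <- g$means[2] + k_sd * g$sds[2]
  t_low <- max(0, g$means[1] - k_sd * g$sds[1])
  if (t_low >= t_high)
    stop("computed t_low >= t_high: set thresholds manually")
  list(t_low = t_low, t_high = t_high, source = "automatic")
}

#' Flag epochs outside the amplitude thresholds
#'
#' Comparisons are strict: an epoch exactly at a threshold is kept (the
#' thresholds are 4-SD tail bounds, so boundary mass is negligible).
#'
#' @param r per-epoch (smoothed) RMS series.
#' @param t threshold list from [amplitude_thresholds()] or a manual
#'   `list(t_low=, t_high=)`.
#' @return Logical vector of flags with attribute `reason`
#'   (`"amplitude"`/`"none"` per epoch).
#' @export
flag_amplitude_artifacts <- function(r, t) {
  flags <- r < t$t_low | r > t$t_high
  structure(flags, reason = ifelse(flags, "amplitude", "none"))
}

# 2-D Epanechnikov kernel density estimate evaluated at the sample points.
# Radial kernel K(u) = 2/(pi h^2) (1 - |u|^2/h^2)+ with Scott's-rule
# bandwidth on z-scored data; compact support makes isolated points land at
# density 0 (log-density -Inf), which the -5 threshold flags.
epanechnikov_density <- function(train, query = train, bandwidth = NULL) {
  train <- as.matrix(train); query <- as.matrix(query)
  n <- nrow(train)
  h <- bandwidth %||% n^(-1 / 6) # Scott's rule, d = 2, unit variances
  h2 <- h^2
  norm_const <- 2 / (pi * h2) / n
  dens <- numeric(nrow(query))
  block <- max(1L, floor(2e6 / n))
  for (s in seq(1L, nrow(query), by = block)) {
    idx <- s:min(s + block - 1L, nrow(query))
    d2 <- outer(query[idx, 1], train[, 1], "-")^2 +
      outer(query[idx, 2], train[, 2], "-")^2
    k <- 1 - d2 / h2
    k[k < 0] <- 0
    dens[idx] <- norm_const * rowSums(k)
  }
  dens
}

#' Flag normal-amplitude artifacts by kernel-density outlier detection
#'
#' Builds the 2-D feature space (raw per-epoch RMS, summed spectral amplitude
#' over 2-10 Hz), z-scores each dimension, estimates the density with an
#' Epanechnikov kernel (Scott's-rule bandwidth) and flags epochs whose
#' natural-log density falls below `log_density_threshold`. Epochs already
#' flagged by amplitude are excluded from both the fit and the flagging.
#'
#' @param r_raw raw (unsmoothed) per-epoch RMS.
#' @param spectra an `epoch_spectra` object (see [epoch_spectra()]).
#' @param log_density_threshold flagging threshold on the natural log of the
#'   estimated density (default -5).
#' @param exclude logical vector of epochs to leave out (e.g. amplitude
#'   flags); they are never flagged here.
#' @param bandwidth optional kernel bandwidth override.
#' @return Logical flag vector (full epoch length) with attribute `reason`.
#' @export
flag_density_artifacts <- function(r_raw, spectra, log_density_threshold = -5,
                                   exclude = NULL,
                                   bandwidth = NULL) {
  n <- length(r_raw)
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  use <- which(!exclude)
  if (length(use) < 50L)
    stop("fewer than 50 usable epochs: kernel density estimate is unstable")
  bsum <- extract_band(spectra, band(2, 10), summed = TRUE)
  feat <- cbind(r_raw[use], bsum[use])
  feat <- scale(feat)
  dens <- epanechnikov_density(feat, bandwidth = bandwidth)
  flags <- rep(FALSE, n)
  flags[use] <- log(dens) < log_density_threshold
  structure(flags, reason = ifelse(flags, "density", "none"))
}

#' Detect artifact epochs (amplitude + density)
#'
#' Convenience wrapper running the full artifact stage: 20-s RMS smoothing,
#' 2-component GMM with `M +/- 4 sigma` thresholds, then Epanechnikov KDE
#' outlier flagging on the remaining epochs.
#'
#' @param x an `epoched_signal`.
#' @param spectra matching `epoch_spectra`.
#' @param smoothing_halfwidth RMS smoothing half-width in epochs (default 1,
#'   i.e. a 3-epoch / 20-s-reach window for 10-s epochs).
#' @param k_sd amplitude tail width (default 4).
#' @param log_density_threshold KDE log-density threshold (default -5).
#' @param manual_thresholds optional `list(t_low=, t_high=)` bypassing the GMM.
#' @param seed initialization seed.
#' @return List with `flags` (logical), `reason` (character per epoch),
#'   `thresholds`, `rms_raw`, `rms_smooth`.
#' @export
detect_artifacts <- function(x, spectra, smoothing_halfwidth = 1L,
                             k_sd = 4, log_density_threshold = -5,
                             manual_thresholds = NULL, seed = 42L) {
  r_raw <- epoch_rms(x)
  r_sm <- smooth_rms(r_raw, smoothing_halfwidth)
  thr <- if (!is.null(manual_thresholds)) {
    c(manual_thresholds, list(source = "manual"))
  } else {
    amplitude_thresholds(fit_rms_gmm(r_sm, seed = seed), k_sd = k_sd)
  }
  amp <- flag_amplitude_artifacts(r_sm, thr)
  den <- flag_density_artifacts(r_raw, spectra,
                                log_density_threshold = log_density_threshold,
                                exclude = as.logical(amp))
  flags <- as.logical(amp) | as.logical(den)
  reason <- rep("none", length(flags))
  reason[as.logical(den)] <- "density"
  reason[as.logical(amp)] <- "amplitude"
  list(flags = flags, reason = reason, thresholds = thr,
       rms_raw = r_raw, rms_smooth = r_sm)
}

#' Restore artifact epochs in a scored hypnogram
#'
#' Each flagged epoch takes the label of the closest preceding non-flagged
#' epoch; a flagged run at the start of the record takes the closest
#' following label, so the output contains no `ART` labels.
#'
#' @param h a [hypnogram()] scored on non-artifact epochs.
#' @param mask logical artifact flags, same length as `h`.
#' @return A [hypnogram()] without artifact labels.
#' @export
restore_artifact_epochs <- function(h, mask) {
  stopifnot(inherits(h, "hypnogram"), length(mask) == length(h$labels))
  if (all(mask)) stop("all epochs are flagged as artifacts: nothing to restore")
  lab <- h$labels
  lab[mask] <- NA_character_
  # forward fill
  for (i in seq_along(lab)) {
    if (is.na(lab[i]) && i > 1L) lab[i] <- lab[i - 1L]
  }
  # leading run: backward fill
  if (is.na(lab[1])) {
    first <- which(!is.na(lab))[1]
    lab[seq_len(first - 1L)] <- lab[first]
  }
  hypnogram(lab, epoch_len_s = h$epoch_len_s)
}
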
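#' Stage percentages over consecutive windows
#'
#' @param h a [hypnogram()].
#' @param window_s window length in seconds; must be a multiple of the
#'   epoch length. A trailing partial window is normalized by its own size.
#' @return Data frame: window start (s), and per-stage fractions summing
#'   to 1 in every row.
#' @export
stage_percentages <- function(h, window_s = 3600) {
  stopifnot(inherits(h, "hypnogram"))
  per <- window_s / h$epoch_len_s
  if (abs(per - round(per)) > 1e-9)
    stop("window_s must be a multiple of the epoch length")
  per <- round(per)
  n <- length(h$labels)
  grp <- (seq_len(n) - 1L) %/% per
  out <- do.call(rbind, lapply(split(h$labels, grp), function(lab) {
    tab <- table(factor(lab, levels = STAGES)) / length(lab)
    as.numeric(tab)
  }))
  data.frame(window_start_s = sort(unique(grp)) * window_s,
             W = out[, 1], NR = out[, 2], R = out[, 3])
}

#' Stage fragmentation statistics
#'
#' Run-length statistics of continuous same-stage episodes.
#'
#' @param h a [hypnogram()].
#' @return Data frame per stage: bout count, mean/median/max bout length in
#'   epochs.
#' @export
fragmentation_stats <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  runs <- stage_runs(h$labels)
  out <- do.call(rbind, lapply(STAGES, function(s) {
    len <- runs$length[runs$stage == s]
    if (length(len) == 0L)
      data.frame(stage = s, n_bouts = 0L, mean_epochs = NA_real_,
                 median_epochs = NA_real_, max_epochs = NA_integer_)
    else
      data.frame(stage = s, n_bouts = length(len), mean_epochs = mean(len),
                 median_epochs = median(len), max_epochs = max(len))
  }))
  rownames(out) <- NULL
  out
}

#' Stage counts per light/dark period
#'
#' @param h a [hypnogram()].
#' @param period_s period length in seconds (default 12 h).
#' @param light_first does the recording start with the light period?
#' @return Data frame: period index, period label, per-stage epoch counts.
#' @export
stage_counts <- function(h, period_s = 43200, light_first = TRUE) {
  stopifnot(inherits(h, "hypnogram"))
  per <- period_s / h$epoch_len_s
  if (abs(per - round(per)) > 1e-9)
    stop("period_s must be a multiple of the epoch length")
  grp <- (seq_along(h$labels) - 1L) %/% round(per)
  lab2 <- if (light_first) c("light", "dark") else c("dark", "light")
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    tab <- table(factor(h$labels[grp == g], levels = STAGES))
    data.frame(period = g + 1L, phase = lab2[(g %% 2) + 1L],
               W = tab[["W"]], NR = tab[["NR"]], R = tab[["R"]])
  }))
  rownames(out) <- NULL
  out
}

#' Per-stage band power with artifact exclusion
#'
#' Mean summed band amplitude per stage, computed over non-artifact epochs
#' only (artifact epochs are excluded from spectral averages even after
#' their stages are restored).
#'
#' @param s an `epoch_spectra`.
#' @param h the scored [hypnogram()].
#' @param b a [band()] (e.g. delta, `band(1, 4)`).
#' @param artifact_mask logical per-epoch artifact flags (default none).
#' @return List: `per_epoch` (summed band amplitude, `NA` at artifacts) and
#'   `per_stage` (named means).
#' @export
stage_band_power <- function(s, h, b, artifact_mask = NULL) {
  stopifnot(inherits(h, "hypnogram"))
  v <- extract_band(s, b, summed = TRUE)
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, length(v))
  v[artifact_mask] <- NA
  per_stage <- vapply(STAGES, function(st)
    mean(v[h$labels == st], na.rm = TRUE), numeric(1))
  list(per_epoch = v, per_stage = per_stage)
}

#' Sensitivity screen over candidate bands or band combinations
#'
#' For NREM mode, each candidate band is used alone in the per-band GMM
#' classifier and scored against the reference (NREM sensitivity and
#' mix-W/R sensitivity); candidates reaching 0.9 on both are flagged
#' efficient. For REM mode, each candidate BC runs the two-step GMM on the
#' wake-reduced retained set and its REM sensitivity (recall over all
#' reference REM epochs) is reported.
#'
#' @param spectra an `epoch_spectra` of the recording.
#' @param reference reference [hypnogram()].
#' @param candidates list of [band()]s (`mode = "nrem"`) or BCs
#'   (`mode = "rem"`).
#' @param mode `"nrem"` or `"rem"`.
#' @param artifact_mask optional logical exclusions.
#' @param retained for `mode = "rem"`: logical retained mask over
#'   non-artifact epochs from [reduce_wake()]; computed on the fly from the
#'   recording RMS when omitted requires `rms`.
#' @param rms raw per-epoch RMS (needed to derive `retained` when absent).
#' @param smoothing_halfwidth NREM chunk smoothing (epochs).
#' @param seed initialization seed.
#' @return Data frame sorted by decreasing target-state sensitivity, with
#'   an `efficient` flag in NREM mode.
#' @export
band_sensitivity_screen <- function(spectra, reference, candidates,
                                    mode = c("nrem", "rem"),
                                    artifact_mask = NULL,
                                    retained = NULL, rms = NULL,
                                    smoothing_halfwidth = 1L, seed = 42L) {
  mode <- match.arg(mode)
  if (is.null(reference)) stop("a reference hypnogram is required")
  n_ep <- nrow(spectra$amplitudes)
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, n_ep)
  use <- which(!artifact_mask)
  ref <- reference$labels[use]

  if (mode == "nrem") {
    rows <- lapply(seq_along(candidates), function(j) {
      b <- candidates[[j]]
      chunk <- extract_band(spectra, b, summed = FALSE)[use, , drop = FALSE]
      if (smoothing_halfwidth > 0)
        chunk <- smooth_features_time(chunk, smoothing_halfwidth)
      v <- tryCatch(classify_band_nrem(chunk, seed = seed),
                    error = function(e) rep(NA_integer_, length(use)))
      sens_nr <- mean(v[ref == "NR"] == 1L)
      sens_mix <- mean(v[ref != "NR"] == 0L)
      data.frame(lo = b[["lo"]], hi = b[["hi"]],
                 sens_nrem = sens_nr, sens_mix = sens_mix,
                 efficient = isTRUE(sens_nr >= 0.9 && sens_mix >= 0.9))
    })
    out <- do.call(rbind, rows)
    out[order(-out$sens_nrem), ]
  } else {
    if (is.null(retained)) {
      if (is.null(rms)) stop("supply either `retained` or `rms` for REM mode")
      wr <- reduce_wake(smooth_rms(rms[use], 1L),
                        epoch_len_s = reference$epoch_len_s, seed = seed)
      retained <- wr$retained
    }
    ret <- which(retained)
    n_rem_total <- sum(ref == "R")
    rows <- lapply(seq_along(candidates), function(j) {
      bc <- candidates[[j]]
      th <- extract_band(spectra, bc$theta, summed = TRUE)[use][ret]
      ds <- extract_band(spectra, bc$ds, summed = TRUE)[use][ret]
      lab <- bc_classify_rem(th, ds, seed = seed)
      sens <- if (is.null(lab) || n_rem_total == 0) NA_real_
      else sum(lab & ref[ret] == "R") / n_rem_total
      data.frame(theta_lo = bc$theta[["lo"]], theta_hi = bc$theta[["hi"]],
                 ds_lo = bc$ds[["lo"]], ds_hi = bc$ds[["hi"]],
                 sens_rem = sens)
    })
    out <- do.call(rbind, rows)
    out[order(-out$sens_rem), ]
  }
}
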
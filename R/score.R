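#' Scoring configuration
#'
#' Bundles every tunable parameter of the scoring pipeline. Species presets
#' change the NREM voting bands and the number of REM band combinations
#' (rats separate well with few BCs; mice need more).
#'
#' @param species `"rat"` or `"mouse"`.
#' @param epoch_len_s epoch length in seconds (default 10).
#' @param highpass apply the 2-Hz zero-phase FIR high-pass before scoring?
#'   Default `FALSE`; enable for recordings with pronounced slow drift.
#' @param highpass_cutoff,highpass_transition filter parameters in Hz.
#' @param artifact_smoothing_halfwidth RMS smoothing half-width (epochs) for
#'   amplitude-artifact thresholding (default 1, i.e. a 20-s-reach window).
#' @param artifact_k_sd amplitude threshold tail width in component SDs
#'   (default 4).
#' @param log_density_threshold KDE log-density threshold (default -5).
#' @param manual_artifact_thresholds optional `list(t_low=, t_high=)`
#'   bypassing the artifact GMM.
#' @param nrem_bands band list or preset name for [nrem_detect()].
#' @param nrem_smoothing_halfwidth chunk time-smoothing half-width (epochs).
#' @param wide_halfwidth_s wake-reduction smoothing half-width, seconds
#'   (150-300 recommended with the automatic threshold; default 150).
#' @param threshold_drop_fraction wake-reduction threshold drop (default 0.10).
#' @param post_crossing_remove ascending-slope epochs removed per upward
#'   crossing (default 45).
#' @param manual_wake_threshold optional manual wake-reduction threshold.
#' @param bcs list of band combinations (default [default_bcs()] for the
#'   species).
#' @param n_bcs number of BCs used for voting (default 4 for rats, 15 for
#'   mice; capped at `length(bcs)`).
#' @param stringency_fraction REM voting stringency: an epoch is REM when
#'   its vote count strictly exceeds this fraction of the voting BCs.
#'   Species default: 0.75 for rats (unanimity over the 4 default BCs,
#'   which best suppresses transitional false positives), 0.5 (strict
#'   majority) for mice.
#' @param ellipse_magnification SD-ellipse scale factor (default 1.5);
#'   `NA` disables the ellipse correction.
#' @param iterations 1 or 2 (default 2: run the refinement iteration).
#' @param rule_wake_history_enabled,rule_singleton_enabled contextual rule
#'   switches (both default `TRUE`).
#' @param wake_lookback,wake_min wake-history rule parameters (20, 10).
#' @param seed seed for all GMM initializations.
#' @return Object of class `score_config`.
#' @export
score_config <- function(species = c("rat", "mouse"),
                         epoch_len_s = 10,
                         highpass = FALSE,
                         highpass_cutoff = 2,
                         highpass_transition = 0.6,
                         artifact_smoothing_halfwidth = 1L,
                         artifact_k_sd = 4,
                         log_density_threshold = -5,
                         manual_artifact_thresholds = NULL,
                         nrem_bands = NULL,
                         nrem_smoothing_halfwidth = 1L,
                         wide_halfwidth_s = 150,
                         threshold_drop_fraction = 0.10,
                         post_crossing_remove = 45L,
                         manual_wake_threshold = NULL,
                         bcs = NULL,
                         n_bcs = NULL,
                         stringency_fraction = NULL,
                         ellipse_magnification = 1.5,
                         iterations = 2L,
                         rule_wake_history_enabled = TRUE,
                         rule_singleton_enabled = TRUE,
                         wake_lookback = 20L,
                         wake_min = 10L,
                         seed = 42L) {
  species <- match.arg(species)
  if (!iterations %in% 1:2) stop("iterations must be 1 or 2")
  if (threshold_drop_fraction < 0 || threshold_drop_fraction >= 1)
    stop("threshold_drop_fraction must be in [0, 1)")
  bcs <- bcs %||% default_bcs(species)
  n_bcs <- min(n_bcs %||% if (species == "rat") 4L else 15L, length(bcs))
  stringency_fraction <- stringency_fraction %||%
    if (species == "rat") 0.75 else 0.5
  if (n_bcs < 2L) stop("need at least 2 band combinations")
  structure(list(
    species = species, epoch_len_s = epoch_len_s,
    highpass = highpass, highpass_cutoff = highpass_cutoff,
    highpass_transition = highpass_transition,
    artifact_smoothing_halfwidth = artifact_smoothing_halfwidth,
    artifact_k_sd = artifact_k_sd,
    log_density_threshold = log_density_threshold,
    manual_artifact_thresholds = manual_artifact_thresholds,
    nrem_bands = nrem_bands %||% species,
    nrem_smoothing_halfwidth = nrem_smoothing_halfwidth,
    wide_halfwidth_s = wide_halfwidth_s,
    threshold_drop_fraction = threshold_drop_fraction,
    post_crossing_remove = post_crossing_remove,
    manual_wake_threshold = manual_wake_threshold,
    bcs = bcs, n_bcs = n_bcs,
    stringency_fraction = stringency_fraction,
    ellipse_magnification = ellipse_magnification,
    iterations = as.integer(iterations),
    rule_wake_history_enabled = rule_wake_history_enabled,
    rule_singleton_enabled = rule_singleton_enabled,
    wake_lookback = wake_lookback, wake_min = wake_min,
    seed = as.integer(seed)), class = "score_config")
}

#' @export
print.score_config <- function(x, ...) {
  cat(sprintf("Scoring config (%s preset): %g-s epochs, %d iteration(s)\n",
              x$species, x$epoch_len_s, x$iterations))
  cat(sprintf("  wake reduction: %g-s half-width, drop %.0f%%, %d post-crossing epochs\n",
              x$wide_halfwidth_s, 100 * x$threshold_drop_fraction,
              x$post_crossing_remove))
  cat(sprintf("  REM voting: %d BCs, stringency %.2f, ellipse x%.2g\n",
              x$n_bcs, x$stringency_fraction, x$ellipse_magnification))
  invisible(x)
}

# One REM identification pass over the retained epochs. All index vectors
# are in "use space" (non-artifact epochs). Returns the REM mask over use
# space plus the audit pieces.
.rem_pass <- function(wr, theta_feats, ds_feats, cfg) {
  ret <- which(wr$retained)
  votes <- lapply(seq_len(cfg$n_bcs), function(j) {
    bc_classify_rem(theta_feats[ret, j], ds_feats[ret, j],
                    seed = cfg$seed + j)
  })
  sv <- stringency_vote(votes, cfg$stringency_fraction)
  counts <- attr(sv, "vote_count")
  avg <- bc_average_features(theta_feats[ret, , drop = FALSE],
                             ds_feats[ret, , drop = FALSE])
  rem_ret <- as.logical(sv)
  ellipse <- NULL
  if (is.finite(cfg$ellipse_magnification)) {
    ellipse <- tryCatch(
      fit_rem_ellipse(avg$theta, avg$ds, counts,
                      magnification = cfg$ellipse_magnification),
      error = function(e) {
        warning("ellipse correction skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(ellipse))
      rem_ret <- apply_ellipse_correction(rem_ret, ellipse, avg$theta, avg$ds)
  }
  rem_use <- logical(length(wr$retained))
  rem_use[ret[rem_ret]] <- TRUE
  list(rem_use = rem_use, vote_count = counts, ellipse = ellipse,
       retained = wr$retained, avg_features = avg)
}

#' Score a recording into wake, NREM and REM sleep
#'
#' Runs the full pipeline: sampling-rate regularization, optional high-pass,
#' epoching, artifact detection (amplitude thresholds + KDE outliers),
#' per-band GMM voting for NREM, wide-window wake reduction, per-BC
#' two-step GMM REM classification with stringency voting and SD-ellipse
#' correction, contextual rules, an optional second refinement iteration,
#' and artifact-epoch restoration. REM assignment overrides a previous NREM
#' label in the merge.
#'
#' @param rec an [eeg_recording()] (or a `psg_truth` bundle, whose
#'   recording is then scored).
#' @param config a [score_config()].
#' @return Object of class `somnoscore_fit` with elements `hypnogram`
#'   (final, artifact-free), `artifacts`, `nrem`, `iterations` (per-pass
#'   audit: wake reduction, vote counts, ellipse, REM mask),
#'   `intermediate_hypnograms`, `config`.
#' @examples
#' \donttest{
#' sim <- simulate_psg(sim_config(duration_s = 4 * 3600, seed = 11))
#' fit <- score_psg(sim$recording, score_config("rat"))
#' print(fit)
#' evaluate_scoring(fit$hypnogram, sim$hypnogram)
#' }
#' @export
score_psg <- function(rec, config = score_config()) {
  if (inherits(rec, "psg_truth")) rec <- rec$recording
  stopifnot(inherits(rec, "eeg_recording"), inherits(config, "score_config"))
  cfg <- config

  rec <- regularize_fs(rec)
  if (cfg$highpass)
    rec <- highpass_eeg(rec, cfg$highpass_cutoff, cfg$highpass_transition)
  x <- epoch_signal(rec, cfg$epoch_len_s)
  n_ep <- nrow(x)
  spectra <- epoch_spectra(x)

  art <- detect_artifacts(
    x, spectra,
    smoothing_halfwidth = cfg$artifact_smoothing_halfwidth,
    k_sd = cfg$artifact_k_sd,
    log_density_threshold = cfg$log_density_threshold,
    manual_thresholds = cfg$manual_artifact_thresholds,
    seed = cfg$seed)
  use <- which(!art$flags)
  if (length(use) < 50L) stop("artifact detection left too few usable epochs")

  nrem_lab <- nrem_detect(spectra, bands = cfg$nrem_bands,
                          artifact_mask = art$flags,
                          smoothing_halfwidth = cfg$nrem_smoothing_halfwidth,
                          seed = cfg$seed)

  # wake reduction operates on the 20-s-smoothed RMS of the usable epochs
  r_use <- smooth_rms(art$rms_raw[use], cfg$artifact_smoothing_halfwidth)
  wr <- reduce_wake(r_use, epoch_len_s = cfg$epoch_len_s,
                    wide_halfwidth_s = cfg$wide_halfwidth_s,
                    threshold_drop_fraction = cfg$threshold_drop_fraction,
                    post_crossing_remove = cfg$post_crossing_remove,
                    manual_threshold = cfg$manual_wake_threshold,
                    seed = cfg$seed)

  sel_bcs <- cfg$bcs[seq_len(cfg$n_bcs)]
  theta_feats <- vapply(sel_bcs, function(bc)
    extract_band(spectra, bc$theta, summed = TRUE)[use], numeric(length(use)))
  ds_feats <- vapply(sel_bcs, function(bc)
    extract_band(spectra, bc$ds, summed = TRUE)[use], numeric(length(use)))

  base_use <- ifelse(nrem_lab[use] == 1L, "NR", "W")
  apply_rules <- function(lab_use) {
    h <- hypnogram(lab_use, cfg$epoch_len_s)
    if (cfg$rule_wake_history_enabled)
      h <- rule_wake_history(h, cfg$wake_lookback, cfg$wake_min)
    h <- rule_drop_singleton_rem(h, cfg$rule_singleton_enabled)
    h$labels
  }

  iterations <- list()
  intermediates <- list()
  pass <- .rem_pass(wr, theta_feats, ds_feats, cfg)
  lab_use <- base_use
  lab_use[pass$rem_use] <- "R" # REM overrides NREM in the merge
  lab_use <- apply_rules(lab_use)
  iterations[[1]] <- c(pass, list(wake_reduction = wr))
  intermediates[[1]] <- lab_use

  if (cfg$iterations == 2L) {
    wr2 <- second_iteration_trim(wr, lab_use == "R")
    pass2 <- .rem_pass(wr2, theta_feats, ds_feats, cfg)
    lab_use <- base_use
    lab_use[pass2$rem_use] <- "R"
    lab_use <- apply_rules(lab_use)
    iterations[[2]] <- c(pass2, list(wake_reduction = wr2))
    intermediates[[2]] <- lab_use
  }

  full <- rep(STAGE_ART, n_ep)
  full[use] <- lab_use
  final <- restore_artifact_epochs(hypnogram(full, cfg$epoch_len_s),
                                   art$flags)

  structure(list(hypnogram = final,
                 artifacts = art,
                 nrem = nrem_lab,
                 iterations = iterations,
                 intermediate_hypnograms = intermediates,
                 use_index = use,
                 fs = rec$fs,
                 config = cfg,
                 call = match.call()),
            class = "somnoscore_fit")
}

#' @export
print.somnoscore_fit <- function(x, ...) {
  cat("Automatic vigilance-state scoring\n")
  print(x$hypnogram)
  cat(sprintf("  artifact epochs restored: %d (%.1f%%)\n",
              sum(x$artifacts$flags), 100 * mean(x$artifacts$flags)))
  invisible(x)
}

#' @export
summary.somnoscore_fit <- function(object, ...) {
  x <- object
  print(x)
  thr <- x$artifacts$thresholds
  cat(sprintf("  amplitude thresholds (%s): [%.3g, %.3g]\n",
              thr$source, thr$t_low, thr$t_high))
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    cat(sprintf("  iteration %d: %d retained epochs, %d REM epochs%s\n",
                i, sum(it$retained), sum(it$rem_use),
                if (is.null(it$ellipse)) " (no ellipse)" else ""))
  }
  frag <- fragmentation_stats(x$hypnogram)
  cat("  bout statistics:\n")
  print(frag)
  invisible(x)
}

#' Plot a scored recording
#'
#' Two panels: the wide-smoothed RMS with the wake-reduction threshold, and
#' the final hypnogram.
#'
#' @param x a `somnoscore_fit`.
#' @param ... passed to the RMS panel's `plot`.
#' @export
plot.somnoscore_fit <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(op))
  wr <- x$iterations[[1]]$wake_reduction
  sm <- rep(NA_real_, length(x$artifacts$flags))
  # smoothed series lives in use space; place it back on the epoch axis
  sm[x$use_index] <- wr$smoothed_wide
  t_h <- (seq_along(sm) - 0.5) * x$config$epoch_len_s / 3600
  plot(t_h, sm, type = "l", xlab = "", ylab = "wide-smoothed RMS",
       main = "wake reduction", ...)
  abline(h = wr$threshold, lty = 2)
  lvl <- c(W = 1, NR = 2, R = 3)
  y <- lvl[x$hypnogram$labels]
  plot(t_h, y, type = "s", yaxt = "n", ylim = c(0.5, 3.5),
       xlab = "time (h)", ylab = "", main = "hypnogram")
  axis(2, at = 1:3, labels = names(lvl), las = 1)
  invisible(x)
}
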
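#' Per-band GMM classification of NREM sleep
#'
#' Fits a 2-component full-covariance Gaussian mixture to the raw
#' multi-column spectral chunk of one frequency band (epochs x bins, no
#' summing) and labels the component with the greater mean total amplitude
#' as NREM (1), the other as the wake/REM mixture (0). For delta and sigma
#' bands the higher-amplitude component is NREM by physiology; the same
#' rule is applied to any user-supplied band, but pure theta bands are a
#' poor NREM discriminant and should be avoided.
#'
#' The attached `separation_ratio` attribute (higher over lower component
#' mean total) quantifies how distinct the components are: NREM's amplitude
#' advantage in its defining bands is large (a factor of 2-5), whereas
#' splitting a homogeneous state yields components differing only by the
#' slow amplitude drift (~20\%). With `min_ratio` above 1 the band abstains
#' (all-zero votes, `abstained` attribute) when the ratio falls below it;
#' [nrem_detect()] instead applies this test globally across its bands.
#'
#' @param chunk numeric matrix of band amplitudes, epochs in rows (see
#'   [extract_band()] with `summed = FALSE`).
#' @param seed initialization seed.
#' @param band_label optional label used in error messages.
#' @param min_ratio minimum separation ratio below which the band abstains
#'   (default 1: never abstain).
#' @return Integer vector of per-epoch votes (1 = NREM, 0 = mix-W/R).
#' @export
classify_band_nrem <- function(chunk, seed = 42L, band_label = NULL,
                               min_ratio = 1) {
  chunk <- as.matrix(chunk)
  fit <- tryCatch(fit_gmm_nd(chunk, seed = seed), error = function(e) {
    stop(sprintf("NREM GMM failed for band %s: %s",
                 band_label %||% "<unnamed>", conditionMessage(e)))
  })
  totals <- colSums(fit$means) # mean total amplitude per component
  nrem_comp <- which.max(totals)
  out <- as.integer(fit$classification == nrem_comp)
  ratio <- max(totals) / min(totals)
  if (ratio < min_ratio) {
    out <- integer(nrow(chunk))
    attr(out, "abstained") <- TRUE
  }
  attr(out, "separation_ratio") <- ratio
  out
}

#' Majority vote across per-band classifications
#'
#' An epoch is NREM when strictly more than half of the bands vote NREM;
#' exact ties go to the wake/REM mixture (false NREM is harder to undo in
#' the downstream REM step than false mix).
#'
#' @param votes list of equal-length 0/1 vectors (or a matrix with one band
#'   per column).
#' @return Integer 0/1 vector.
#' @export
majority_vote <- function(votes) {
  if (is.matrix(votes)) votes <- lapply(seq_len(ncol(votes)), function(j) votes[, j])
  if (length(votes) == 0L) stop("no band votes supplied")
  len <- unique(vapply(votes, length, 1L))
  if (length(len) != 1L) stop("band votes differ in length")
  counts <- Reduce(`+`, votes)
  as.integer(counts > length(votes) / 2)
}

#' Named NREM band presets
#'
#' Band sets recommended for rats and mice. `"comb1"`: the five 1-Hz sigma
#' bands 11-16 Hz; `"comb2"`: 2-3, 3-4 Hz plus the sigma set; `"comb3"`:
#' all 1-Hz bands 2-16 Hz; `"comb4"`: 2-3, 3-4 and 2-4 Hz. `"rat"` and
#' `"mouse"` both map to `"comb2"`, the best sensitivity balance for the
#' NREM vs. mix classification in either species.
#'
#' @param name preset name.
#' @return List of [band()] objects.
#' @export
nrem_band_preset <- function(name = c("rat", "mouse", "comb1", "comb2",
                                      "comb3", "comb4")) {
  name <- match.arg(name)
  if (name %in% c("rat", "mouse")) name <- "comb2"
  sigma <- lapply(11:15, function(lo) band(lo, lo + 1))
  switch(name,
         comb1 = sigma,
         comb2 = c(list(band(2, 3), band(3, 4)), sigma),
         comb3 = lapply(2:15, function(lo) band(lo, lo + 1)),
         comb4 = list(band(2, 3), band(3, 4), band(2, 4)))
}

#' Detect NREM epochs by per-band GMM clustering and majority voting
#'
#' For each band: extract the raw spectral chunk, optionally RMS-smooth it
#' along time, fit the 2-component GMM on non-artifact epochs, and vote;
#' the majority across bands gives the NREM / mix-W/R split. Artifact
#' epochs are excluded from fitting and returned as `NA`.
#'
#' @param s an `epoch_spectra`.
#' @param bands list of [band()]s or a preset name for [nrem_band_preset()].
#' @param artifact_mask logical per-epoch exclusions (default none).
#' @param smoothing_halfwidth time-smoothing half-width in epochs applied to
#'   the chunk before clustering (default 1; 0 disables).
#' @param seed initialization seed.
#' @param min_separation_ratio if no band separates two components whose
#'   mean total amplitudes differ by at least this factor, the record is
#'   treated as containing no NREM sleep instead of being partitioned
#'   arbitrarily (default 1.5; see [classify_band_nrem()]).
#' @return Integer vector per epoch: 1 = NREM, 0 = mix-W/R, `NA` = artifact;
#'   attribute `votes` holds the epoch-by-band vote matrix.
#' @export
nrem_detect <- function(s, bands = "rat", artifact_mask = NULL,
                        smoothing_halfwidth = 1L, seed = 42L,
                        min_separation_ratio = 1.5) {
  if (is.character(bands)) bands <- nrem_band_preset(bands)
  n_ep <- nrow(s$amplitudes)
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, n_ep)
  use <- which(!artifact_mask)
  votes <- matrix(NA_integer_, nrow = n_ep, ncol = length(bands))
  ratios <- numeric(length(bands))
  for (j in seq_along(bands)) {
    b <- bands[[j]]
    # artifact rows are dropped before smoothing so contaminated spectra
    # never leak into their neighbors
    chunk <- extract_band(s, b, summed = FALSE)[use, , drop = FALSE]
    if (smoothing_halfwidth > 0)
      chunk <- smooth_features_time(chunk, smoothing_halfwidth)
    v <- classify_band_nrem(
      chunk, seed = seed,
      band_label = sprintf("[%g, %g)", b[["lo"]], b[["hi"]]))
    ratios[j] <- attr(v, "separation_ratio") %||% NA_real_
    votes[use, j] <- v
  }
  out <- rep(NA_integer_, n_ep)
  if (all(is.na(ratios)) || max(ratios, na.rm = TRUE) < min_separation_ratio) {
    # no band separates a distinctly higher-amplitude component: the record
    # is scored as free of NREM sleep rather than partitioned arbitrarily
    warning("no NREM band separates a distinct high-amplitude component; ",
            "labeling no epochs as NREM")
    out[use] <- 0L
  } else {
    out[use] <- majority_vote(votes[use, , drop = FALSE])
  }
  attr(out, "votes") <- votes
  attr(out, "separation_ratios") <- ratios
  out
}
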
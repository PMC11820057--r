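#' Per-epoch RMS amplitude
#'
#' The root-mean-square of each epoch's samples, the backbone of both
#' amplitude-artifact detection and wake reduction.
#'
#' @param x an `epoched_signal` (see [epoch_signal()]) or a numeric matrix
#'   with one epoch per row.
#' @return Numeric vector, one nonnegative value per epoch.
#' @export
epoch_rms <- function(x) {
  sqrt(rowMeans(x^2))
}

#' RMS smoothing of a per-epoch series
#'
#' Replaces each value by the root of the mean of squares over a symmetric
#' window of `2w + 1` epochs. At the series edges the window is truncated and
#' the normalizer reduced to the actual window size, so a constant series is
#' a fixed point and `w = 0` is the identity. The same operator smooths raw
#' RMS series (20-s window, `w = 1`, before artifact thresholding), spectral
#' band features along time, and the wide-window wake-reduction series
#' (`w` of 15-30 epochs).
#'
#' @param r numeric vector (nonnegative per-epoch values).
#' @param halfwidth_epochs integer window half-width `w >= 0`, in epochs.
#' @return Numeric vector of the same length.
#' @export
smooth_rms <- function(r, halfwidth_epochs) {
  w <- as.integer(halfwidth_epochs)
  if (w < 0) stop("halfwidth_epochs must be >= 0")
  if (w == 0L || length(r) == 1L) return(r)
  n <- length(r)
  cs <- cumsum(c(0, r^2))
  lo <- pmax(seq_len(n) - w, 1L)
  hi <- pmin(seq_len(n) + w, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Columnwise RMS smoothing of a feature matrix along time
#'
#' Applies [smooth_rms()] to every column of an epochs-by-features matrix
#' (epochs in rows). Used to temporally smooth spectral band chunks before
#' clustering, which reduces hypnogram fragmentation.
#'
#' @param features numeric matrix, epochs in rows.
#' @param halfwidth_epochs window half-width in epochs.
#' @return Matrix of the same dimensions.
#' @export
smooth_features_time <- function(features, halfwidth_epochs) {
  if (is.null(dim(features))) return(smooth_rms(features, halfwidth_epochs))
  apply(features, 2, smooth_rms, halfwidth_epochs = halfwidth_epochs)
}
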
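#' Frequency band
#'
#' Half-open interval `[lo, hi)` over spectral bin centers, so adjacent
#' bands partition the axis without double counting.
#'
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return Object of class `eeg_band` (named numeric of length 2).
#' @export
band <- function(lo, hi) {
  if (!(lo > 0 && hi > lo)) stop("band requires 0 < lo < hi")
  structure(c(lo = as.numeric(lo), hi = as.numeric(hi)), class = "eeg_band")
}

#' @export
print.eeg_band <- function(x, ...) {
  cat(sprintf("band [%g, %g) Hz\n", x[["lo"]], x[["hi"]])); invisible(x)
}

#' Per-epoch amplitude spectra (Welch-style, Hanning, 50\% overlap)
#'
#' For each epoch, 256-sample Hanning-windowed segments hopped by 128 samples
#' are Fourier-transformed and their amplitude spectra (|DFT|, not power)
#' averaged; only nonnegative frequencies are kept. Window normalization
#' constants are omitted: they cancel in the z-scoring/clustering downstream.
#'
#' @param x an `epoched_signal` (epoch length must be >= 256 samples).
#' @param nfft segment length in samples (default 256).
#' @return An `epoch_spectra`: list with `amplitudes`
#'   (`n_epochs x n_freq_bins`), `freqs` (Hz, spacing `fs/nfft`), `fs`,
#'   `nfft`.
#' @export
epoch_spectra <- function(x, nfft = 256L) {
  fs <- attr(x, "fs")
  spe <- ncol(x)
  if (spe < nfft) stop("epoch shorter than the FFT segment length")
  hop <- nfft %/% 2L
  starts <- seq(1L, spe - nfft + 1L, by = hop)
  n_seg <- length(starts)
  n_ep <- nrow(x)
  win <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))) # Hanning
  n_bins <- nfft %/% 2L + 1L
  amp <- matrix(0, nrow = n_ep, ncol = n_bins)
  for (s in starts) {
    seg <- t(x[, s:(s + nfft - 1L), drop = FALSE]) * win # nfft x n_ep
    amp <- amp + t(Mod(mvfft(seg))[seq_len(n_bins), , drop = FALSE])
  }
  amp <- amp / n_seg
  structure(list(amplitudes = amp,
                 freqs = (0:(nfft %/% 2L)) * fs / nfft,
                 fs = fs, nfft = nfft, n_segments = n_seg),
            class = "epoch_spectra")
}

#' @export
print.epoch_spectra <- function(x, ...) {
  cat(sprintf("Epoch spectra: %d epochs x %d bins (0-%g Hz, %g Hz spacing)\n",
              nrow(x$amplitudes), length(x$freqs), max(x$freqs),
              x$fs / x$nfft))
  invisible(x)
}

#' Extract a frequency-band feature from epoch spectra
#'
#' Bin membership is by bin center in `[lo, hi)`.
#'
#' @param s an `epoch_spectra`.
#' @param b an [band()].
#' @param summed if `TRUE`, return the per-epoch scalar sum over the band's
#'   bins; if `FALSE` (default), the multi-column sub-matrix of raw bin
#'   amplitudes (used unsummed for NREM clustering).
#' @return Numeric vector (`summed = TRUE`) or matrix.
#' @export
extract_band <- function(s, b, summed = FALSE) {
  sel <- which(s$freqs >= b[["lo"]] & s$freqs < b[["hi"]])
  if (length(sel) == 0L)
    stop(sprintf("band [%g, %g) Hz contains no spectral bins",
                 b[["lo"]], b[["hi"]]))
  m <- s$amplitudes[, sel, drop = FALSE]
  if (summed) rowSums(m) else m
}

#' Enumerate candidate bands on an integer-Hz grid
#'
#' All bands `(lo, lo + width)` with `lo` in `[lo_min, lo_max]`, `width` in
#' `[width_min, width_max]` and `lo + width <= f_cap`, sorted by `(lo, hi)`.
#' The canonical catalogues are `enumerate_bands(2, 14, 2, 14, 16)`
#' (91 delta/sigma bands) and `enumerate_bands(5, 9, 1, 5, 10)`
#' (15 theta bands).
#'
#' @param lo_min,lo_max left-border range, Hz.
#' @param width_min,width_max band width range, Hz.
#' @param f_cap maximum right border, Hz.
#' @return List of [band()] objects (possibly empty).
#' @export
enumerate_bands <- function(lo_min, lo_max, width_min, width_max, f_cap) {
  out <- list()
  if (lo_max >= lo_min && width_max >= width_min) {
    for (lo in seq(lo_min, lo_max)) {
      for (wd in seq(width_min, width_max)) {
        if (lo + wd <= f_cap) out[[length(out) + 1L]] <- band(lo, lo + wd)
      }
    }
  }
  out
}

#' Standard delta/sigma and theta band catalogues
#'
#' @param type `"delta_sigma"` (91 bands, 2-16 Hz) or `"theta"`
#'   (15 bands, 5-10 Hz).
#' @return List of [band()] objects.
#' @export
band_catalogue <- function(type = c("delta_sigma", "theta")) {
  switch(match.arg(type),
         delta_sigma = enumerate_bands(2, 14, 2, 14, 16),
         theta = enumerate_bands(5, 9, 1, 5, 10))
}

#' Enumerate theta vs. delta/sigma band combinations (BCs)
#'
#' Full Cartesian product in theta-major order. With the standard catalogues
#' this yields 15 x 91 = 1365 combinations.
#'
#' @param theta_bands,ds_bands nonempty lists of [band()]s.
#' @return List of BCs, each `list(theta = band, ds = band)`.
#' @export
enumerate_bcs <- function(theta_bands, ds_bands) {
  if (length(theta_bands) == 0L || length(ds_bands) == 0L)
    stop("both band lists must be nonempty")
  out <- vector("list", length(theta_bands) * length(ds_bands))
  k <- 0L
  for (th in theta_bands) {
    for (ds in ds_bands) {
      k <- k + 1L
      out[[k]] <- list(theta = th, ds = ds)
    }
  }
  out
}
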
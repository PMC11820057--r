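#' Single-channel EEG recording
#'
#' @param samples numeric vector of EEG samples (microvolts or any
#'   consistent unit).
#' @param fs sampling rate in Hz (positive; may be non-integer, see
#'   [regularize_fs()]).
#' @param channel channel name.
#' @param start_time optional `POSIXct` recording start.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel = "EEG", start_time = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("recording must contain samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number")
  structure(list(samples = samples, fs = fs, channel = channel,
                 start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording '%s': %d samples at %g Hz (%.2f h)\n",
              x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs / 3600))
  invisible(x)
}

#' Load a recording from EDF or delimited text
#'
#' @param path input file.
#' @param format `"edf"` or `"csv"`. CSV/plain text is one sample per line
#'   (an optional non-numeric header line is skipped) and requires
#'   `fs_override` because the format carries no sampling rate.
#' @param fs_override sampling rate in Hz; required for csv, overrides the
#'   header value for EDF when given.
#' @param channel optional channel name to select (EDF); default first
#'   channel.
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path, format = c("edf", "csv"),
                           fs_override = NULL, channel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read %s file: %s (not found)", format, path))
  if (format == "csv") {
    if (is.null(fs_override))
      stop("csv input carries no sampling rate; supply fs_override")
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    vals <- suppressWarnings(as.numeric(lines))
    if (length(vals) > 0 && is.na(vals[1])) { # header line
      lines <- lines[-1]
      vals <- suppressWarnings(as.numeric(lines))
    }
    if (anyNA(vals))
      stop(sprintf("cannot parse csv file %s: non-numeric sample on line %d",
                   path, which(is.na(vals))[1]))
    eeg_recording(vals, fs = fs_override,
                  channel = channel %||% "EEG")
  } else {
    edf <- read_edf(path)
    nm <- names(edf$signals)
    if (is.null(channel)) {
      idx <- 1L
    } else {
      idx <- match(channel, nm)
      if (is.na(idx))
        stop(sprintf("channel '%s' not present in %s (channels: %s)",
                     channel, path, paste(nm, collapse = ", ")))
    }
    eeg_recording(edf$signals[[idx]],
                  fs = fs_override %||% edf$fs[idx],
                  channel = nm[idx], start_time = edf$start_time)
  }
}

#' Round a non-integer sampling rate to the nearest integer
#'
#' Non-integer rates prevent exact epoching; the signal is polyphase-resampled
#' (via [signal::resample()]) to `round(fs)`. Integer rates pass through
#' unchanged, so the operation is idempotent.
#'
#' @param rec an [eeg_recording()].
#' @return An [eeg_recording()] with integer `fs`.
#' @export
regularize_fs <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  target <- round(fs)
  if (isTRUE(all.equal(fs, target))) {
    rec$fs <- target
    return(rec)
  }
  # rational approximation of target/fs for polyphase resampling
  frac <- .rat_approx(target / fs)
  y <- signal::resample(rec$samples, p = frac[1], q = frac[2])
  n_out <- round(length(rec$samples) * target / fs)
  if (length(y) >= n_out) y <- y[seq_len(n_out)]
  else y <- c(y, rep(y[length(y)], n_out - length(y)))
  eeg_recording(y, fs = target, channel = rec$channel,
                start_time = rec$start_time)
}

# Continued-fraction rational approximation p/q of x with q bounded.
.rat_approx <- function(x, max_q = 10000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_q) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    r <- 1 / (r - a)
    if (!is.finite(r)) break
  }
  c(as.integer(p1), as.integer(q1))
}

#' Zero-phase FIR high-pass filter
#'
#' Hamming-window FIR design with the length rule `ceil(3.3 / (transition/fs))`
#' forced odd, applied forward and backward (FFT-based) for zero phase. Used
#' to suppress slow drifts and movement-related low-frequency artifacts before
#' scoring; off by default in [score_config()] because the scored bands start
#' at 2 Hz.
#'
#' @param rec an [eeg_recording()].
#' @param cutoff high-pass cutoff in Hz (default 2).
#' @param transition transition width in Hz (default 0.6).
#' @return Filtered [eeg_recording()] of identical length.
#' @export
highpass_eeg <- function(rec, cutoff = 2, transition = 0.6) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff + transition >= fs / 2)
    stop("cutoff + transition must be below the Nyquist frequency")
  ntaps <- ceiling(3.3 / (transition / fs))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  # fir1 order = ntaps - 1 (even => type-I, valid for high-pass)
  b <- signal::fir1(ntaps - 1, cutoff / (fs / 2), type = "high")
  y <- .filtfilt_fir(b, rec$samples)
  rec$samples <- y
  rec
}

# Zero-phase FIR filtering: FFT convolution forward, then on the reversed
# signal, with edge padding of half the kernel to suppress transients.
.filtfilt_fir <- function(b, x) {
  nb <- length(b)
  half <- (nb - 1) %/% 2
  pad <- min(half, length(x) - 1L)
  xp <- c(rev(x[seq_len(pad) + 1L]), x,
          rev(x[length(x) - seq_len(pad)]))
  one_pass <- function(v) {
    y <- signal::fftfilt(b, c(v, numeric(half)))
    y[(half + 1):(half + length(v))]
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1):(pad + length(x))]
}

#' Split a recording into fixed-length epochs
#'
#' @param rec an [eeg_recording()] with integer sampling rate.
#' @param epoch_len_s epoch length in seconds (default 10).
#' @return An `epoched_signal`: numeric matrix `n_epochs x samples_per_epoch`
#'   with attributes `fs` and `epoch_len_s`. Rows are contiguous,
#'   non-overlapping slices; a trailing partial epoch is discarded.
#' @export
epoch_signal <- function(rec, epoch_len_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("sampling rate must be integer; call regularize_fs() first")
  fs <- round(fs)
  if (epoch_len_s <= 0) stop("epoch_len_s must be positive")
  spe <- fs * epoch_len_s
  if (abs(spe - round(spe)) > 1e-9)
    stop("fs * epoch_len_s must be an integer number of samples")
  spe <- round(spe)
  n_ep <- length(rec$samples) %/% spe
  if (n_ep < 1L) stop("signal shorter than one epoch")
  m <- matrix(rec$samples[seq_len(n_ep * spe)], nrow = n_ep, ncol = spe,
              byrow = TRUE)
  structure(m, fs = fs, epoch_len_s = epoch_len_s, class = "epoched_signal")
}

#' @export
print.epoched_signal <- function(x, ...) {
  cat(sprintf("Epoched signal: %d epochs x %d samples (%g s at %d Hz)\n",
              nrow(x), ncol(x), attr(x, "epoch_len_s"), attr(x, "fs")))
  invisible(x)
}
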
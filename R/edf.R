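# Minimal European Data Format (EDF) support: 16-bit continuous records,
# enough to interchange single/multi-channel rodent EEG. None of the
# pre-installed packages reads EDF, and the layout is fixed-width, so the
# ~100 lines below implement it directly against the published header spec.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write signals to an EDF file
#'
#' Signals are quantized to 16-bit integers over their physical range and
#' stored in 1-second data records; a trailing partial second is dropped.
#'
#' @param signals a numeric vector or a named list of numeric vectors
#'   (one per channel; equal durations).
#' @param fs sampling rate in Hz (integer; shared by all channels).
#' @param path output file.
#' @param phys_dim physical dimension string (default "uV").
#' @param start_time optional `POSIXct` used for the header date/time.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, phys_dim = "uV",
                      start_time = NULL) {
  if (is.numeric(signals)) signals <- list(EEG = signals)
  ns <- length(signals)
  if (is.null(names(signals)))
    names(signals) <- paste0("CH", seq_len(ns))
  fs <- as.integer(round(fs))
  n_rec <- min(vapply(signals, length, 1L)) %/% fs
  if (n_rec < 1L) stop("signal shorter than one EDF record (1 s)")
  st <- start_time %||% as.POSIXct("2000-01-01 00:00:00", tz = "UTC")

  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]][seq_len(n_rec * fs)]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    pmin_[i] <- lo; pmax_[i] <- hi
    dig[[i]] <- as.integer(round((x - lo) / (hi - lo) * 65534 - 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X X X X", 80), .edf_pad("Startdate X X X X", 80),
    .edf_pad(format(st, "%d.%m.%y"), 8), .edf_pad(format(st, "%H.%M.%S"), 8),
    .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(1, 8), .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, .edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(names(signals), 16)
  field(rep("", ns), 80)
  field(rep(phys_dim, ns), 8)
  field(formatC(pmin_, digits = 6, format = "g"), 8)
  field(formatC(pmax_, digits = 6, format = "g"), 8)
  field(rep(-32767, ns), 8)
  field(rep(32767, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns))
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file.
#' @return A list with `signals` (named list of numeric vectors in physical
#'   units), `fs` (per-channel sampling rate, Hz) and `start_time`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read edf file: ", path, " (not found)")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8); rd(80); rd(80)
  date <- rd(8); time <- rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("cannot parse edf header of ", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  st <- tryCatch(
    as.POSIXct(paste(date, time), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL)
  signals <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      scale <- (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      signals[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin_[i] + (d - dmin[i]) * scale
    }
  }
  names(signals) <- labels
  list(signals = signals, fs = spr / rec_dur, start_time = st)
}
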
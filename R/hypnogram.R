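#' Per-epoch vigilance-state labels
#'
#' A hypnogram is the sequence of vigilance-state labels ("W" wake, "NR" NREM
#' sleep, "R" REM sleep, plus the transient bookkeeping label "ART" for
#' artifact epochs) scored over consecutive fixed-length epochs.
#'
#' @param labels character vector of stage tokens, one per epoch; allowed
#'   tokens are `"W"`, `"NR"`, `"R"` and `"ART"`.
#' @param epoch_len_s epoch length in seconds (default 10).
#' @return An object of class `hypnogram`: a list with elements `labels`
#'   (character) and `epoch_len_s`.
#' @examples
#' h <- hypnogram(c("W", "W", "NR", "NR", "R"))
#' table(h$labels)
#' @export
hypnogram <- function(labels, epoch_len_s = 10) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- !labels %in% c(STAGES, STAGE_ART)
  if (any(bad)) {
    stop(sprintf("unknown stage token '%s' at epoch %d",
                 labels[which(bad)[1]], which(bad)[1]))
  }
  if (!is.numeric(epoch_len_s) || epoch_len_s <= 0)
    stop("epoch_len_s must be positive")
  structure(list(labels = labels, epoch_len_s = epoch_len_s),
            class = "hypnogram")
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("Hypnogram: %d epochs of %g s (%.2f h)\n",
              n, x$epoch_len_s, n * x$epoch_len_s / 3600))
  tab <- table(factor(x$labels, levels = c(STAGES, STAGE_ART)))
  pct <- 100 * tab / n
  for (s in names(tab)) {
    if (tab[[s]] > 0 || s %in% STAGES)
      cat(sprintf("  %-3s %6d epochs (%5.1f%%)\n", s, tab[[s]], pct[[s]]))
  }
  invisible(x)
}

#' Read a plain-text hypnogram file
#'
#' One stage token per line, from the alphabet `W`, `NR`, `R`, `ART`.
#' Blank lines are ignored; any other token is a parse error naming the line.
#'
#' @param path file to read.
#' @param epoch_len_s epoch length in seconds of the stored labels.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_len_s = 10) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  tok <- trimws(raw)
  keep <- nzchar(tok)
  lines <- which(keep)
  tok <- tok[keep]
  bad <- !tok %in% c(STAGES, STAGE_ART)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("unknown stage token '%s' on line %d of %s",
                 tok[i], lines[i], path))
  }
  hypnogram(tok, epoch_len_s = epoch_len_s)
}

#' Write a hypnogram as a plain-text label file
#'
#' @param h a [hypnogram()].
#' @param path output file; one token per line.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  writeLines(h$labels, path)
  invisible(path)
}

# Run-length view of a label vector: data.frame(stage, start, length).
stage_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(stage = r$values,
             start = ends - r$lengths + 1L,
             length = r$lengths,
             stringsAsFactors = FALSE)
}
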
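#' Wake-history contextual rule
#'
#' REM sleep essentially never arises out of a wake-rich context: if ten or
#' more of the twenty epochs preceding an automatically identified REM
#' epoch are wake, the epoch is almost certainly not REM, and the entire
#' containing REM run is relabeled to the state that immediately preceded
#' it. Epochs near the start of the record use whatever history is
#' available; a REM run starting at the first epoch is left unchanged.
#' The rule is idempotent.
#'
#' @param h a scored [hypnogram()] without `ART` labels.
#' @param lookback history length in epochs (default 20).
#' @param wake_min wake-epoch count triggering the rule (default 10).
#' @return A corrected [hypnogram()].
#' @export
rule_wake_history <- function(h, lookback = 20L, wake_min = 10L) {
  stopifnot(inherits(h, "hypnogram"))
  # runs are processed left to right against the progressively updated
  # labels, which makes a single pass a fixed point (idempotence)
  lab <- h$labels
  runs <- stage_runs(lab)
  for (k in which(runs$stage == "R")) {
    st <- runs$start[k]
    if (st == 1L) next # no preceding state
    idx <- st:(st + runs$length[k] - 1L)
    trig <- any(vapply(idx, function(i) {
      hist <- lab[max(1L, i - lookback):(i - 1L)]
      sum(hist == "W") >= wake_min
    }, logical(1)))
    if (trig) lab[idx] <- lab[st - 1L]
  }
  hypnogram(lab, epoch_len_s = h$epoch_len_s)
}

#' Singleton-REM contextual rule
#'
#' Isolated single REM epochs are replaced by the preceding state (e.g.
#' NR, NR, R, W becomes NR, NR, NR, W); a singleton at the very first
#' epoch takes the following epoch's label instead. Optional in the
#' pipeline; identity when disabled.
#'
#' @param h a scored [hypnogram()].
#' @param enabled apply the rule? (default `TRUE`).
#' @return A corrected [hypnogram()].
#' @export
rule_drop_singleton_rem <- function(h, enabled = TRUE) {
  stopifnot(inherits(h, "hypnogram"))
  if (!enabled) return(h)
  lab0 <- h$labels
  lab <- lab0
  runs <- stage_runs(lab0)
  for (k in which(runs$stage == "R" & runs$length == 1L)) {
    i <- runs$start[k]
    lab[i] <- if (i > 1L) lab0[i - 1L]
    else if (length(lab0) > 1L) lab0[2L] else lab0[i]
  }
  hypnogram(lab, epoch_len_s = h$epoch_len_s)
}
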
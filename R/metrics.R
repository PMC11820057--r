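#' Compare an automatic hypnogram to an expert reference
#'
#' Computes the standard agreement metrics for three-class sleep scoring:
#' general accuracy (fraction of equal labels), balanced accuracy (mean
#' one-vs-rest recall), per-class one-vs-rest accuracy (with per-class
#' recall also reported, since usage of "accuracy by class" varies),
#' per-class F1 and Cohen's kappa (one-vs-rest), macro-averaged F1, the
#' multiclass Cohen's kappa, and the confusion matrix (expert in rows).
#'
#' @param auto automatic [hypnogram()].
#' @param expert reference [hypnogram()] of equal length and epoch size.
#' @param classes stage labels considered (default W, NR, R).
#' @return Object of class `scoring_metrics` (a list of the quantities
#'   above).
#' @export
evaluate_scoring <- function(auto, expert, classes = c("W", "NR", "R")) {
  stopifnot(inherits(auto, "hypnogram"), inherits(expert, "hypnogram"))
  if (length(auto$labels) != length(expert$labels))
    stop("hypnograms differ in length")
  if (!isTRUE(all.equal(auto$epoch_len_s, expert$epoch_len_s)))
    stop("hypnograms differ in epoch length")
  a <- factor(auto$labels, levels = classes)
  e <- factor(expert$labels, levels = classes)
  n <- length(a)
  cm <- table(expert = e, auto = a)

  accuracy <- mean(a == e)
  per_class <- lapply(classes, function(cl) {
    tp <- sum(a == cl & e == cl)
    fp <- sum(a == cl & e != cl)
    fn <- sum(a != cl & e == cl)
    tn <- n - tp - fp - fn
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    p_obs <- (tp + tn) / n
    p_exp <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
    kappa <- if (p_exp < 1) (p_obs - p_exp) / (1 - p_exp) else 0
    c(accuracy = p_obs, recall = recall, precision = precision,
      f1 = f1, kappa = kappa)
  })
  pc <- do.call(rbind, per_class)
  rownames(pc) <- classes

  balanced_accuracy <- mean(pc[, "recall"], na.rm = TRUE)
  macro_f1 <- mean(pc[, "f1"])
  p_obs <- accuracy
  p_exp <- sum(rowSums(cm) * colSums(cm)) / n^2
  general_kappa <- if (p_exp < 1) (p_obs - p_exp) / (1 - p_exp) else 0

  structure(list(accuracy = accuracy,
                 balanced_accuracy = balanced_accuracy,
                 per_class = pc,
                 macro_f1 = macro_f1,
                 general_kappa = general_kappa,
                 confusion = cm,
                 n_epochs = n),
            class = "scoring_metrics")
}

#' @export
print.scoring_metrics <- function(x, ...) {
  cat(sprintf("Scoring agreement over %d epochs\n", x$n_epochs))
  cat(sprintf("  general accuracy : %.3f\n", x$accuracy))
  cat(sprintf("  balanced accuracy: %.3f\n", x$balanced_accuracy))
  cat(sprintf("  macro F1         : %.3f\n", x$macro_f1))
  cat(sprintf("  Cohen's kappa    : %.3f\n", x$general_kappa))
  cat("  per class:\n")
  print(round(x$per_class, 3))
  cat("  confusion matrix (expert in rows):\n")
  print(x$confusion)
  invisible(x)
}
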
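# Thin deterministic wrappers around mclust's 2-component Gaussian mixtures.
# All clustering steps of the pipeline go through these, so seeding and
# degenerate-input policy live in one place. For large samples, model-based
# hierarchical initialization runs on a seeded subset (EM still uses all
# points), keeping fits reproducible and fast.

.gmm_subset <- function(n, seed, max_init = 1500L) {
  if (n <= max_init) return(NULL)
  with_seed(seed, sample.int(n, max_init))
}

#' Two-component 1-D Gaussian mixture, components sorted by mean
#'
#' @param x numeric vector (>= 20 points for a meaningful split).
#' @param seed integer seed for the (subset) initialization.
#' @param min_n minimum number of points required.
#' @return A `gmm_split`: list with `means`, `sds`, `weights` (low component
#'   first), `assignments` (1 = low, 2 = high) and `posterior_high`.
#' @export
fit_gmm_1d <- function(x, seed = 42L, min_n = 20L) {
  x <- as.numeric(x)
  if (length(x) < min_n)
    stop(sprintf("need at least %d points for a 2-component GMM", min_n))
  if (sd(x) < .Machine$double.eps^0.5 || length(unique(x)) < 3L)
    stop("degenerate input (no variance): set thresholds manually")
  init <- .gmm_subset(length(x), seed)
  fit <- suppressWarnings(Mclust(
    x, G = 2, modelNames = "V", verbose = FALSE,
    initialization = if (is.null(init)) NULL else list(subset = init)))
  if (is.null(fit) || fit$G != 2)
    stop("2-component GMM fit failed: set thresholds manually")
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1L) sig <- rep(sig, 2)
  pro <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  cls <- match(fit$classification, ord)
  post_high <- fit$z[, ord[2]]
  structure(list(means = mu[ord], sds = sig[ord], weights = pro[ord],
                 assignments = cls, posterior_high = post_high),
            class = "gmm_split")
}

#' @export
print.gmm_split <- function(x, ...) {
  cat(sprintf(
    "2-component GMM: low N(%.3g, %.3g^2) w=%.2f | high N(%.3g, %.3g^2) w=%.2f\n",
    x$means[1], x$sds[1], x$weights[1], x$means[2], x$sds[2], x$weights[2]))
  invisible(x)
}

# Equal-posterior decision boundary between the two components, searched
# between the component means. Falls back to the variance-weighted midpoint
# if the posteriors do not cross there (extreme weight imbalance).
gmm_boundary <- function(g) {
  f <- function(x) {
    log(g$weights[1]) + dnorm(x, g$means[1], g$sds[1], log = TRUE) -
      log(g$weights[2]) - dnorm(x, g$means[2], g$sds[2], log = TRUE)
  }
  lo <- g$means[1]; hi <- g$means[2]
  if (hi - lo < .Machine$double.eps) return(mean(c(lo, hi)))
  if (f(lo) > 0 && f(hi) < 0) {
    uniroot(f, c(lo, hi), tol = 1e-9 * (hi - lo))$root
  } else {
    (g$sds[2] * lo + g$sds[1] * hi) / sum(g$sds)
  }
}

# Two-component full-covariance GMM on a multi-column feature chunk.
# Returns per-point component labels plus each component's mean vector.
fit_gmm_nd <- function(xmat, seed = 42L) {
  xmat <- as.matrix(xmat)
  if (nrow(xmat) < 4L) stop("too few epochs for GMM clustering")
  if (all(apply(xmat, 2, sd) < .Machine$double.eps^0.5))
    stop("degenerate input (no variance) for GMM clustering")
  init <- .gmm_subset(nrow(xmat), seed)
  model <- if (ncol(xmat) == 1L) "V" else "VVV"
  fit <- suppressWarnings(Mclust(
    xmat, G = 2, modelNames = model, verbose = FALSE,
    initialization = if (is.null(init)) NULL else list(subset = init)))
  if (is.null(fit) || fit$G != 2) stop("2-component GMM fit failed")
  mu <- fit$parameters$mean
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  # per-component variance of the total-amplitude projection (1' Sigma 1)
  var_total <- if (ncol(xmat) == 1L) {
    as.numeric(fit$parameters$variance$sigmasq)
  } else {
    sig <- fit$parameters$variance$sigma
    c(sum(sig[, , 1]), sum(sig[, , 2]))
  }
  if (length(var_total) == 1L) var_total <- rep(var_total, 2)
  list(classification = fit$classification, means = mu,
       var_total = var_total)
}
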
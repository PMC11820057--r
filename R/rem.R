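#' Wake-epoch reduction by wide-window RMS thresholding
#'
#' The per-epoch RMS series is smoothed with a wide window (half-width
#' 150-300 s). Because REM sleep immediately follows NREM sleep, wide
#' smoothing flattens the sharp RMS drop at the NREM-to-REM transition, so
#' REM epochs stay in the high-RMS regime while consolidated wake remains
#' low. A 2-component GMM splits the smoothed series; the equal-posterior
#' boundary between the components, lowered by `threshold_drop_fraction` of
#' the inter-mean gap (so that essentially no REM epoch is lost), is the
#' retention threshold. Epochs at or below it are dropped, and at each
#' upward threshold crossing the next `post_crossing_remove` retained
#' epochs — the ascending RMS slope, populated by wake and early NREM — are
#' dropped as well.
#'
#' @param r per-epoch RMS series (artifact epochs already excluded).
#' @param epoch_len_s epoch length in seconds.
#' @param wide_halfwidth_s smoothing half-width in seconds (default 150).
#' @param threshold_drop_fraction fraction of the inter-component mean gap
#'   subtracted from the boundary (default 0.10).
#' @param post_crossing_remove retained epochs removed after each upward
#'   crossing (default 45).
#' @param manual_threshold optional threshold overriding the GMM.
#' @param seed initialization seed.
#' @return A `wake_reduction` object: `retained` (final logical mask),
#'   `retained_threshold` (mask after thresholding only, before the
#'   ascending-slope removal), `threshold`, `smoothed_wide`, `gmm`,
#'   `crossings` (indices of upward threshold crossings).
#' @export
reduce_wake <- function(r, epoch_len_s = 10, wide_halfwidth_s = 150,
                        threshold_drop_fraction = 0.10,
                        post_crossing_remove = 45L,
                        manual_threshold = NULL, seed = 42L) {
  w <- max(1L, round(wide_halfwidth_s / epoch_len_s))
  sm <- smooth_rms(r, w)
  if (is.null(manual_threshold)) {
    g <- fit_gmm_1d(sm, seed = seed)
    thr <- gmm_boundary(g) -
      threshold_drop_fraction * (g$means[2] - g$means[1])
  } else {
    g <- NULL
    thr <- manual_threshold
  }
  above <- sm > thr
  crossings <- which(above & !c(TRUE, head(above, -1))) # below -> above
  retained <- above
  for (cidx in crossings) {
    run_end <- cidx
    while (run_end < length(above) && above[run_end + 1L]) run_end <- run_end + 1L
    cut_end <- min(cidx + post_crossing_remove - 1L, run_end)
    retained[cidx:cut_end] <- FALSE
  }
  # proximity warning: REM-risk condition when much of the just-retained
  # mass sits within 5% of the threshold
  near <- retained & sm < thr * 1.05
  if (mean(near[retained]) > 0.25 && sum(retained) > 0)
    warning("many retained epochs sit within 5% of the wake-reduction ",
            "threshold; REM epochs may be at risk - consider a manual threshold")
  structure(list(retained = retained, retained_threshold = above,
                 threshold = thr, smoothed_wide = sm, gmm = g,
                 halfwidth_epochs = w, crossings = crossings),
            class = "wake_reduction")
}

#' @export
print.wake_reduction <- function(x, ...) {
  cat(sprintf(
    "Wake reduction: threshold %.3g, %d/%d epochs retained (%.1f%%), %d crossings\n",
    x$threshold, sum(x$retained), length(x$retained),
    100 * mean(x$retained), length(x$crossings)))
  invisible(x)
}

#' Second-iteration trim of the retained set
#'
#' Within each above-threshold segment, epochs between the threshold
#' crossings and the nearest first-iteration REM epochs (both flanks, i.e.
#' the ascending and descending RMS slopes) are dropped; the REM epochs
#' themselves and everything between the segment's first and last REM
#' epoch are kept. Segments without first-iteration REM are unchanged. The
#' result is always a subset of the first-iteration retained set.
#'
#' @param res a `wake_reduction` from [reduce_wake()].
#' @param rem_labels_iter1 logical vector (same indexing as `res$retained`)
#'   marking first-iteration REM epochs.
#' @return A `wake_reduction` with an updated `retained` mask.
#' @export
second_iteration_trim <- function(res, rem_labels_iter1) {
  stopifnot(inherits(res, "wake_reduction"),
            length(rem_labels_iter1) == length(res$retained))
  keep <- res$retained
  runs <- stage_runs(ifelse(res$retained, "in", "out"))
  for (k in which(runs$stage == "in")) {
    idx <- runs$start[k]:(runs$start[k] + runs$length[k] - 1L)
    rem_here <- idx[rem_labels_iter1[idx]]
    if (length(rem_here) == 0L) next
    drop <- idx[idx < min(rem_here) | idx > max(rem_here)]
    keep[drop] <- FALSE
  }
  res$retained <- keep
  res
}

#' Two-step GMM REM classification for one band combination
#'
#' Step 1: a 1-D 2-component GMM on the summed delta/sigma feature of the
#' retained epochs; the higher-mean component (the NREM bulk) is removed.
#' Step 2: a 1-D 2-component GMM on the summed theta feature of the
#' remainder; the higher-theta ("rightmost") component is REM. A degenerate
#' fit at either step makes the combination abstain (`NULL`).
#'
#' @param theta_sum,ds_sum per-epoch summed band amplitudes over the
#'   retained epochs.
#' @param seed initialization seed.
#' @return Logical REM labels over the retained epochs, or `NULL` on
#'   abstention (with a message attribute on the condition).
#' @export
bc_classify_rem <- function(theta_sum, ds_sum, seed = 42L) {
  stopifnot(length(theta_sum) == length(ds_sum))
  step1 <- tryCatch(fit_gmm_1d(ds_sum, seed = seed),
                    error = function(e) NULL)
  if (is.null(step1)) return(NULL)
  keep <- step1$assignments == 1L # drop the higher-delta (NREM) component
  if (sum(keep) < 20L) return(NULL)
  step2 <- tryCatch(fit_gmm_1d(theta_sum[keep], seed = seed),
                    error = function(e) NULL)
  if (is.null(step2)) return(NULL)
  rem <- logical(length(theta_sum))
  rem[which(keep)[step2$assignments == 2L]] <- TRUE
  rem
}

#' Stringency voting across band combinations
#'
#' An epoch is REM when its number of REM votes strictly exceeds
#' `stringency_fraction` of the effective (non-abstaining) combination
#' count; `stringency_fraction = 1` requires unanimity. The default 0.5 is
#' the strict majority: exactly half the votes is not enough.
#'
#' @param votes list of logical vectors from [bc_classify_rem()]; `NULL`
#'   entries (abstentions) are dropped and shrink the effective count.
#' @param stringency_fraction fraction in (0, 1].
#' @return Logical REM mask; attribute `vote_count` carries per-epoch counts
#'   and `n_effective` the number of voting combinations.
#' @export
stringency_vote <- function(votes, stringency_fraction = 0.5) {
  votes <- Filter(Negate(is.null), votes)
  if (length(votes) == 0L) stop("all band combinations abstained")
  if (length(votes) < 2L) stop("need at least 2 non-abstaining band combinations")
  if (stringency_fraction <= 0 || stringency_fraction > 1)
    stop("stringency_fraction must be in (0, 1]")
  counts <- Reduce(`+`, votes)
  n_eff <- length(votes)
  rem <- if (stringency_fraction >= 1) counts >= n_eff
  else counts > stringency_fraction * n_eff
  structure(rem, vote_count = counts, n_effective = n_eff)
}

#' Default band combinations per species
#'
#' Theta vs. delta/sigma pairs selected with the packaged sensitivity
#' screen ([band_sensitivity_screen()]) on synthetic reference recordings,
#' constrained to the effective ranges for each species: theta bands with
#' 7 Hz centrally positioned (bands excluding 7 Hz or with it at a border
#' are markedly less sensitive), and narrow low-delta bands that do not
#' overlap the theta range, so the step-1 delta split never absorbs REM
#' epochs. Rats need few combinations (default 4); mice need more
#' (default 15).
#'
#' @param species `"rat"` or `"mouse"`.
#' @return List of BCs (`list(theta=, ds=)`).
#' @export
default_bcs <- function(species = c("rat", "mouse")) {
  species <- match.arg(species)
  if (species == "rat") {
    list(list(theta = band(6, 8), ds = band(3, 5)),
         list(theta = band(6, 9), ds = band(3, 6)),
         list(theta = band(5, 8), ds = band(3, 5)),
         list(theta = band(5, 9), ds = band(4, 6)))
  } else {
    thetas <- list(band(6, 8), band(6, 9), band(5, 8), band(5, 9), band(6, 10))
    dss <- list(band(3, 5), band(3, 6), band(4, 6))
    enumerate_bcs(thetas, dss)
  }
}

#' Fit the REM-cluster standard-deviation ellipse
#'
#' A single Gaussian (sample mean and covariance) is fitted to the
#' averaged-across-BCs (theta, delta/sigma) features of the high-stringency
#' REM epochs — those whose vote count reaches at least 80% of the maximum
#' observed count, a set that closely tracks expert-scored REM. The ellipse
#' is the 1-SD Mahalanobis contour scaled by `magnification`.
#'
#' @param avg_theta,avg_ds averaged z-scored features per retained epoch.
#' @param vote_count per-epoch REM vote counts (see [stringency_vote()]).
#' @param magnification contour scale factor (default 1.5; useful range
#'   roughly 1-1.5).
#' @param high_fraction fraction of the maximum vote count defining the
#'   high-stringency set (default 0.8).
#' @return A `rem_ellipse`: `center`, `covariance`, `magnification`.
#' @export
fit_rem_ellipse <- function(avg_theta, avg_ds, vote_count,
                            magnification = 1.5, high_fraction = 0.8) {
  hi <- vote_count >= high_fraction * max(vote_count)
  if (sum(hi) < 10L)
    stop("fewer than 10 high-stringency REM epochs: draw a manual contour")
  X <- cbind(theta = avg_theta[hi], ds = avg_ds[hi])
  structure(list(center = colMeans(X), covariance = cov(X),
                 magnification = magnification, n_points = sum(hi)),
            class = "rem_ellipse")
}

#' @export
print.rem_ellipse <- function(x, ...) {
  cat(sprintf(
    "REM SD ellipse: center (%.3g, %.3g), magnification %.2g, %d epochs\n",
    x$center[1], x$center[2], x$magnification, x$n_points))
  invisible(x)
}

#' Convert epochs inside the REM ellipse to REM
#'
#' Epochs whose averaged feature point lies within `magnification`
#' Mahalanobis units of the ellipse center are labeled REM regardless of
#' their previous label (this reclaims false-negative REM epochs sitting
#' deep inside the REM cluster); epochs outside are unchanged.
#'
#' @param rem_labels logical REM mask over the retained epochs.
#' @param ellipse a `rem_ellipse`.
#' @param avg_theta,avg_ds the averaged features used for the fit.
#' @return Updated logical mask.
#' @export
apply_ellipse_correction <- function(rem_labels, ellipse, avg_theta, avg_ds) {
  X <- cbind(avg_theta, avg_ds)
  d2 <- mahalanobis(X, ellipse$center, ellipse$covariance)
  rem_labels | sqrt(d2) <= ellipse$magnification
}

#' Manual polygon contour correction
#'
#' All epochs whose averaged feature point falls inside a user-supplied
#' simple closed polygon (even-odd rule; boundary counts as inside) are
#' labeled REM.
#'
#' @param rem_labels logical REM mask over the retained epochs.
#' @param polygon two-column matrix of vertices (theta, delta/sigma), in
#'   order; must be simple (non-self-intersecting) with >= 3 vertices.
#' @param avg_theta,avg_ds averaged features.
#' @return Updated logical mask.
#' @export
manual_contour_correction <- function(rem_labels, polygon, avg_theta, avg_ds) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  if (.polygon_self_intersects(polygon)) stop("polygon is self-intersecting")
  inside <- .point_in_polygon(avg_theta, avg_ds, polygon)
  rem_labels | inside
}

# Even-odd ray casting, vectorized over query points.
.point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  inter <- function(a, b) {
    d1 <- a[2, ] - a[1, ]; d2 <- b[2, ] - b[1, ]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b[1, 1] - a[1, 1]) * d2[2] - (b[1, 2] - a[1, 2]) * d2[1]) / den
    u <- ((b[1, 1] - a[1, 1]) * d1[2] - (b[1, 2] - a[1, 2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1L && j == n) next # adjacent via wrap-around
      if (inter(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

# Averaged z-scored (theta, ds) feature space across the selected BCs.
bc_average_features <- function(theta_feats, ds_feats) {
  zs <- function(m) scale(m)
  list(theta = rowMeans(zs(theta_feats)), ds = rowMeans(zs(ds_feats)))
}
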
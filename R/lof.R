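#' Local Outlier Factor parameters
#'
#' The per-frame candidate sets here are tiny (2-5 instruments give at most
#' 10 axis intersections; time-averaging windows hold 4 or 20 points), which
#' constrains the neighbourhood size: with `k = n - 1` every point's
#' neighbourhood is the whole set and all LOF scores collapse to 1, so no
#' outlier can ever be flagged, while `k = 2` is blind to *pairs* of
#' mutually close aberrant points. The default is therefore adaptive,
#' `k = ceiling(n / 3)` clamped to `[2, n - 2]`: 2 on the 4-6-point sets
#' where the inlier cluster itself is small, growing with the set so that
#' small clumps of aberrant intersections cannot vouch for each other.
#'
#' @param n_neighbors neighbourhood size `k`, clamped to `n - 1` when
#'   applied; `NA` (default) selects the adaptive rule above.
#' @param contamination `"auto"` (flag LOF > 1.5, the usual library
#'   convention) or a fraction in (0, 0.5]: flag the `floor(c * n)` highest
#'   scores.
#' @param min_points_for_lof below this many points LOF is skipped and all
#'   points kept (density ratios on 2-3 points are meaningless).
#' @return A `lof_params` object.
#' @export
lof_params <- function(n_neighbors = NA, contamination = "auto",
                       min_points_for_lof = 4L) {
  n_neighbors <- as.integer(n_neighbors)
  stopifnot(
    "n_neighbors must be >= 1 or NA (adaptive)" =
      is.na(n_neighbors) || n_neighbors >= 1L,
    "min_points_for_lof must be >= 1" = min_points_for_lof >= 1L,
    "contamination must be 'auto' or in (0, 0.5]" =
      identical(contamination, "auto") ||
      (is.numeric(contamination) && contamination > 0 && contamination <= 0.5)
  )
  structure(list(n_neighbors = n_neighbors, contamination = contamination,
                 min_points_for_lof = as.integer(min_points_for_lof)),
            class = "lof_params")
}

## Densities at coincident points are infinite; capped so that ratios between
## two capped densities come out as 1 (duplicates are not outliers).
LRD_CAP <- 1e10

#' Local Outlier Factor scores
#'
#' Density-ratio anomaly scores (Breunig et al. 2000) for a small 2-D point
#' set. Uses the tie-inclusive neighbourhood: all points within the
#' k-distance belong to the neighbourhood, so duplicated distances are
#' handled exactly as the original definition requires. Local reachability
#' densities at coincident points are capped at `1e10`, so clusters of
#' duplicates score 1.
#'
#' @param points `n x 2` matrix of points.
#' @param k neighbourhood size (clamped to `n - 1`).
#' @return Numeric vector of LOF scores (values near 1 = inlier; larger =
#'   more isolated than its neighbours).
#' @export
lof_scores <- function(points, k) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  stopifnot("need at least 2 points for LOF" = n >= 2L, k >= 1L)
  k <- min(as.integer(k), n - 1L)

  d <- as.matrix(stats::dist(pts))
  ## k-distance of each point: k-th smallest distance to another point
  ## (each row includes self at distance 0, hence the (k+1)-th order stat)
  kdist <- vapply(seq_len(n), function(i) sort(d[i, ])[k + 1L], numeric(1))

  neighbours <- lapply(seq_len(n), function(i) {
    nb <- which(d[i, ] <= kdist[i] + 1e-12)
    setdiff(nb, i)
  })
  lrd <- vapply(seq_len(n), function(i) {
    nb <- neighbours[[i]]
    reach <- pmax(kdist[nb], d[i, nb])
    m <- mean(reach)
    if (m <= 0) LRD_CAP else min(1 / m, LRD_CAP)
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    nb <- neighbours[[i]]
    mean(lrd[nb]) / lrd[i]
  }, numeric(1))
}

#' Flag outlier points with LOF
#'
#' Applies the Local Outlier Factor to a candidate point set and returns
#' inlier flags. Sets smaller than `min_points_for_lof` are returned entirely
#' as inliers, and at least one inlier always remains: if every point is
#' flagged, the one with the lowest LOF score is kept.
#'
#' @param points `n x 2` matrix (or list of points), `n >= 1`.
#' @param params a [lof_params()].
#' @return Logical vector: `TRUE` = inlier.
#' @export
exclude_outliers <- function(points, params = lof_params()) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n == 0L) stop("exclude_outliers: empty point set")
  if (n < params$min_points_for_lof) return(rep(TRUE, n))

  k <- if (is.na(params$n_neighbors)) {
    max(2L, min(as.integer(ceiling(n / 3)), n - 2L))
  } else {
    min(params$n_neighbors, n - 1L)
  }
  scores <- lof_scores(pts, k)
  if (identical(params$contamination, "auto")) {
    inlier <- scores <= 1.5
  } else {
    n_out <- floor(params$contamination * n)
    inlier <- rep(TRUE, n)
    if (n_out > 0L) {
      inlier[order(scores, decreasing = TRUE)[seq_len(n_out)]] <- FALSE
    }
  }
  if (!any(inlier)) inlier[which.min(scores)] <- TRUE
  inlier
}
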
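#' Intersect two instrument axes
#'
#' Solves the two-line system for the crossing point of the (infinite) axis
#' lines. Near-parallel axes are rejected before solving: their intersection
#' is numerically unstable and can land arbitrarily far away, so a small
#' angular guard is applied here, separate from the statistical outlier
#' exclusion that LOF performs later.
#'
#' @param a,b [instrument_axis()] objects.
#' @param min_angle reject pairs whose directions differ by less than this
#'   many degrees (mod 180; default 2).
#' @return `c(x, y)`, or `NULL` for (near-)parallel axes.
#' @export
intersect_pair <- function(a, b, min_angle = 2) {
  stopifnot(inherits(a, "instrument_axis"), inherits(b, "instrument_axis"))
  da <- a$direction; db <- b$direction
  cross <- da[1] * db[2] - da[2] * db[1]
  ## |cross| = |sin(angle between directions)|; mod-180 angle
  ang <- asin(pmin(1, abs(cross))) * 180 / pi
  if (ang < min_angle) return(NULL)
  ## a$center + t*da = b$center + s*db
  rhs <- b$center - a$center
  t <- (rhs[1] * db[2] - rhs[2] * db[1]) / cross
  a$center + t * da
}

#' All pairwise axis intersections of a frame
#'
#' Attempts every unordered pair of axes. Two numerical guards apply before
#' the statistical LOF step: near-parallel pairs are skipped
#' ([intersect_pair()]), and intersections farther than
#' `max_distance_factor` times the frame diagonal from the frame centre are
#' dropped (instruments may legitimately converge somewhat off-screen, but
#' not arbitrarily far).
#'
#' @param axes list of [instrument_axis()].
#' @param spec the [frame_spec()].
#' @param min_angle angular guard in degrees (default 2).
#' @param max_distance_factor distance guard as a multiple of the frame
#'   diagonal (default 1.5).
#' @return An `intersection_set`: list with `points` (`m x 2` matrix),
#'   `pair_ids` (`m x 2` matrix of axis indices) and `inlier_flags`
#'   (logical, `NA` until [exclude_outliers()] has been applied).
#' @export
all_intersections <- function(axes, spec, min_angle = 2,
                              max_distance_factor = 1.5) {
  stopifnot(inherits(spec, "frame_spec"))
  n <- length(axes)
  pts <- list(); ids <- list()
  ctr <- frame_center(spec)
  max_d <- max_distance_factor * frame_diagonal(spec)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        p <- intersect_pair(axes[[i]], axes[[j]], min_angle = min_angle)
        if (is.null(p)) next
        if (sqrt(sum((p - ctr)^2)) > max_d) next
        pts[[length(pts) + 1L]] <- p
        ids[[length(ids) + 1L]] <- c(i, j)
      }
    }
  }
  m <- length(pts)
  structure(
    list(points = if (m) do.call(rbind, pts) else matrix(numeric(0), 0, 2),
         pair_ids = if (m) do.call(rbind, ids) else matrix(integer(0), 0, 2),
         inlier_flags = rep(NA, m)),
    class = "intersection_set"
  )
}

#' Centroid of a point set
#'
#' The centre of gravity: the arithmetic mean of the x coordinates and of the
#' y coordinates. This is the final per-frame gaze estimate, taken over the
#' intersections that survive outlier exclusion.
#'
#' @param points `n x 2` matrix or list of points, `n >= 1`.
#' @return `c(x, y)`.
#' @export
centroid <- function(points) {
  pts <- as_point_matrix(points)
  if (nrow(pts) == 0L) stop("centroid: empty point set")
  c(mean(pts[, 1]), mean(pts[, 2]))
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the per-frame estimation stages.
#'
#' @param axis list: `min_elongation`, `min_area` (see [estimate_axis()]).
#' @param intersect list: `min_angle` degrees, `max_distance_factor`.
#' @param lof a [lof_params()].
#' @return A `gaze_config` object.
#' @export
gaze_config <- function(axis = list(min_elongation = 2, min_area = 200),
                        intersect = list(min_angle = 2, max_distance_factor = 1.5),
                        lof = lof_params()) {
  defaults <- list(axis = list(min_elongation = 2, min_area = 200),
                   intersect = list(min_angle = 2, max_distance_factor = 1.5))
  for (sec in names(defaults)) {
    given <- get(sec)
    bad <- setdiff(names(given), names(defaults[[sec]]))
    if (length(bad)) {
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
    }
    defaults[[sec]] <- utils::modifyList(defaults[[sec]], given)
  }
  stopifnot(inherits(lof, "lof_params"))
  structure(c(defaults, list(lof = lof)), class = "gaze_config")
}

new_gaze_estimate <- function(frame_index, timestamp, point = NULL,
                              n_axes = 0L, n_intersections = 0L,
                              n_inliers = 0L, status = "ok") {
  structure(
    list(frame_index = as.integer(frame_index), timestamp = timestamp,
         point = point, n_axes = as.integer(n_axes),
         n_intersections = as.integer(n_intersections),
         n_inliers = as.integer(n_inliers), status = status),
    class = "gaze_estimate"
  )
}

#' @export
print.gaze_estimate <- function(x, ...) {
  loc <- if (!is.null(x$point)) sprintf("(%.1f, %.1f)", x$point[1], x$point[2]) else "-"
  cat(sprintf("<gaze_estimate> #%d %s [%s] axes %d, intersections %d, inliers %d\n",
              x$frame_index, loc, x$status, x$n_axes, x$n_intersections, x$n_inliers))
  invisible(x)
}

#' Estimate the gaze point of one frame
#'
#' Composes the per-frame pipeline: fit all instrument axes, intersect every
#' pair, exclude outlier intersections with LOF, and return the centre of
#' gravity of the remaining intersections as the gaze point. At least two
#' instruments with a usable axis are required; when all pairwise
#' intersections are removed by the numerical guards the frame yields no
#' stable estimate.
#'
#' @param frame an [annotated_frame()].
#' @param config a [gaze_config()].
#' @return A `gaze_estimate` with `status` one of `"ok"`,
#'   `"insufficient_instruments"`, `"no_stable_intersection"`; the point is
#'   present iff the status is `"ok"`.
#' @export
estimate_gaze <- function(frame, config = gaze_config()) {
  stopifnot(inherits(frame, "annotated_frame"), inherits(config, "gaze_config"))
  axes <- axes_for_frame(frame,
                         min_elongation = config$axis$min_elongation,
                         min_area = config$axis$min_area)
  n_axes <- length(axes)
  if (n_axes < 2L) {
    return(new_gaze_estimate(frame$frame_index, frame$timestamp,
                             n_axes = n_axes,
                             status = "insufficient_instruments"))
  }
  xs <- all_intersections(axes, frame$spec,
                          min_angle = config$intersect$min_angle,
                          max_distance_factor = config$intersect$max_distance_factor)
  m <- nrow(xs$points)
  if (m == 0L) {
    return(new_gaze_estimate(frame$frame_index, frame$timestamp,
                             n_axes = n_axes,
                             status = "no_stable_intersection"))
  }
  inlier <- exclude_outliers(xs$points, config$lof)
  new_gaze_estimate(frame$frame_index, frame$timestamp,
                    point = centroid(xs$points[inlier, , drop = FALSE]),
                    n_axes = n_axes, n_intersections = m,
                    n_inliers = sum(inlier), status = "ok")
}

#' Estimate a gaze track over a frame sequence
#'
#' Runs [estimate_gaze()] on each frame and assembles the raw (method 1,
#' no time averaging) gaze track.
#'
#' @param frames list of [annotated_frame()], time-ordered.
#' @param config a [gaze_config()].
#' @return A `gaze_track` data frame with one row per frame and columns
#'   `frame_index, timestamp, x, y, status, n_axes, n_intersections,
#'   n_inliers`.
#' @export
estimate_track <- function(frames, config = gaze_config()) {
  stopifnot(length(frames) >= 1L)
  ests <- lapply(frames, estimate_gaze, config = config)
  df <- data.frame(
    frame_index = vapply(ests, function(e) e$frame_index, integer(1)),
    timestamp = vapply(ests, function(e) e$timestamp, numeric(1)),
    x = vapply(ests, function(e) if (is.null(e$point)) NA_real_ else e$point[1], numeric(1)),
    y = vapply(ests, function(e) if (is.null(e$point)) NA_real_ else e$point[2], numeric(1)),
    status = vapply(ests, function(e) e$status, character(1)),
    n_axes = vapply(ests, function(e) e$n_axes, integer(1)),
    n_intersections = vapply(ests, function(e) e$n_intersections, integer(1)),
    n_inliers = vapply(ests, function(e) e$n_inliers, integer(1)),
    stringsAsFactors = FALSE
  )
  stopifnot("frame indices must be strictly increasing" =
              all(diff(df$frame_index) > 0) || nrow(df) == 1L)
  new_gaze_track(df, spec = frames[[1]]$spec, method = "method1",
                 window = list(n_frames = 1L, mode = "none"))
}
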
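#' Instrument axis
#'
#' The fitted long-axis line of one instrument: the mask centroid, a unit
#' direction (canonicalised so `dy > 0`, or `dx > 0` when `dy == 0`), the two
#' axis end points (the projections onto the axis line of the set pixels with
#' extreme scalar projection) and the elongation, the square root of the
#' ratio of the second-central-moment eigenvalues — for an ideal rectangle
#' this is its length/width ratio.
#'
#' @param center `c(x, y)` centroid.
#' @param direction unit `c(dx, dy)`.
#' @param end_a,end_b axis end points.
#' @param elongation major/minor extent ratio, `>= 1`.
#' @return An `instrument_axis` object.
#' @export
instrument_axis <- function(center, direction, end_a, end_b, elongation = Inf) {
  center <- as_point(center)
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  stopifnot("direction must be a nonzero 2-vector" =
              length(direction) == 2L && is.finite(nrm) && nrm > 0)
  direction <- direction / nrm
  if (direction[2] < 0 || (direction[2] == 0 && direction[1] < 0)) {
    direction <- -direction
  }
  stopifnot("elongation must be >= 1" = elongation >= 1 - 1e-9)
  structure(
    list(center = center, direction = direction,
         end_a = as_point(end_a), end_b = as_point(end_b),
         elongation = elongation),
    class = "instrument_axis"
  )
}

#' @export
print.instrument_axis <- function(x, ...) {
  cat(sprintf(
    "<instrument_axis> center (%.1f, %.1f), dir (%.3f, %.3f), elongation %.2f\n",
    x$center[1], x$center[2], x$direction[1], x$direction[2], x$elongation))
  invisible(x)
}

#' Estimate an instrument's axis from its mask
#'
#' Fits the long-axis line of an instrument from the set pixels of its mask:
#' the centre is the pixel centroid, the direction the principal eigenvector
#' of the 2x2 second-central-moment (covariance) matrix of pixel coordinates,
#' and the ends the projections onto that line of the pixels with minimal and
#' maximal scalar projection. Shapes too small or too round to define an axis
#' are rejected (`NULL`): surgical instruments are long and thin, and a
#' near-isotropic blob has no meaningful direction.
#'
#' @param mask an [instrument_mask()] (polygon masks are rasterized on the
#'   fly).
#' @param spec the [frame_spec()].
#' @param min_elongation reject masks with elongation below this (default 2:
#'   at least twice as long as wide).
#' @param min_area reject masks with fewer set pixels than this (px^2;
#'   default 200 at the reference 1440x1080 resolution — pass a scaled value
#'   for other resolutions, as [axes_for_frame()] does).
#' @return An [instrument_axis()], or `NULL` when the mask fails the filters.
#' @export
estimate_axis <- function(mask, spec, min_elongation = 2, min_area = 200) {
  stopifnot(inherits(mask, "instrument_mask"), inherits(spec, "frame_spec"),
            min_elongation >= 1, min_area > 0)
  px <- mask_pixels(mask, spec)
  n <- length(px$x)
  if (n == 0L) stop("degenerate mask: no set pixels")
  if (n < min_area) return(NULL)

  cx <- mean(px$x); cy <- mean(px$y)
  dx <- px$x - cx; dy <- px$y - cy
  sxx <- sum(dx * dx) / n
  syy <- sum(dy * dy) / n
  sxy <- sum(dx * dy) / n

  tr <- sxx + syy
  det <- sxx * syy - sxy * sxy
  disc <- sqrt(max(0, tr * tr / 4 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(NULL)                    # single pixel / degenerate
  if (disc <= 1e-12 * max(1, tr)) return(NULL) # isotropic: no defined axis
  elong <- sqrt(l1 / max(l2, .Machine$double.eps))
  if (elong < min_elongation) return(NULL)

  ## principal eigenvector of [[sxx, sxy], [sxy, syy]] for eigenvalue l1
  if (abs(sxy) > 1e-12 * max(sxx, syy)) {
    v <- c(l1 - syy, sxy)
  } else if (sxx >= syy) {
    v <- c(1, 0)
  } else {
    v <- c(0, 1)
  }
  v <- v / sqrt(sum(v^2))

  t <- dx * v[1] + dy * v[2]          # scalar projections on the axis
  t_min <- min(t); t_max <- max(t)
  instrument_axis(
    center = c(cx, cy), direction = v,
    end_a = c(cx, cy) + t_min * v,
    end_b = c(cx, cy) + t_max * v,
    elongation = elong
  )
}

#' Axes of all instruments in a frame
#'
#' Runs [estimate_axis()] on every instrument, in order, silently dropping
#' masks that fail the size/elongation filters. `min_area` is specified at
#' the reference 1440x1080 resolution and scaled by the frame-area ratio for
#' other resolutions, so the filter keeps the same physical meaning across
#' the 1440x1080 and 1920x1080 recordings.
#'
#' @param frame an [annotated_frame()].
#' @param min_elongation,min_area filters as in [estimate_axis()]
#'   (`min_area` at the 1440x1080 reference).
#' @return List of [instrument_axis()] (possibly shorter than the
#'   instrument list).
#' @export
axes_for_frame <- function(frame, min_elongation = 2, min_area = 200) {
  stopifnot(inherits(frame, "annotated_frame"))
  spec <- frame$spec
  area_scaled <- min_area * (spec$width * spec$height) / (1440 * 1080)
  axes <- lapply(frame$instruments, function(m) {
    estimate_axis(m, spec, min_elongation = min_elongation,
                  min_area = area_scaled)
  })
  axes[!vapply(axes, is.null, logical(1))]
}
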
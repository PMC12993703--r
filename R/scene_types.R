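#' Frame specification
#'
#' Dimensions and temporal sampling of the video frames. All geometry in the
#' package uses continuous pixel units with a 0-based origin at the top-left
#' corner, x rightward and y downward; the centre of the pixel in column i,
#' row j (1-based matrix indices) is at (i - 0.5, j - 0.5).
#'
#' @param width,height frame size in pixels (positive integers).
#' @param frame_interval seconds between consecutive frames (default 0.25 s,
#'   i.e. 4 fps frame sampling).
#' @return A `frame_spec` object.
#' @examples
#' frame_spec(1440, 1080)
#' @export
frame_spec <- function(width, height, frame_interval = 0.25) {
  width <- as.integer(width)
  height <- as.integer(height)
  stopifnot(
    "width must be a positive integer" = length(width) == 1L && !is.na(width) && width > 0L,
    "height must be a positive integer" = length(height) == 1L && !is.na(height) && height > 0L,
    "frame_interval must be > 0" = is.numeric(frame_interval) && length(frame_interval) == 1L &&
      is.finite(frame_interval) && frame_interval > 0
  )
  structure(
    list(width = width, height = height, frame_interval = frame_interval),
    class = "frame_spec"
  )
}

#' @export
print.frame_spec <- function(x, ...) {
  cat(sprintf("<frame_spec> %d x %d px, %.3g s/frame\n",
              x$width, x$height, x$frame_interval))
  invisible(x)
}

frame_center <- function(spec) c(spec$width / 2, spec$height / 2)

frame_diagonal <- function(spec) sqrt(spec$width^2 + spec$height^2)

## a point is a plain numeric c(x, y); point sets are n x 2 matrices
as_point <- function(p) {
  p <- as.numeric(p)
  stopifnot("a point must be two finite numbers" = length(p) == 2L && all(is.finite(p)))
  p
}

as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2L)
    return(unname(points))
  }
  if (is.list(points)) {
    return(do.call(rbind, lapply(points, as_point)))
  }
  matrix(as_point(points), ncol = 2L)
}

#' Detection box
#'
#' Axis-aligned bounding box with an optional detector confidence, the unit
#' of the IoU/AP50 detection metrics.
#'
#' @param x_min,y_min,x_max,y_max box corners in pixels; `x_min < x_max` and
#'   `y_min < y_max`.
#' @param score detector confidence in `[0, 1]`, `NA` if not available.
#' @return A `detection_box` object.
#' @export
detection_box <- function(x_min, y_min, x_max, y_max, score = NA_real_) {
  stopifnot(
    "degenerate box: need x_min < x_max and y_min < y_max" =
      is.finite(x_min) && is.finite(y_min) && is.finite(x_max) && is.finite(y_max) &&
      x_min < x_max && y_min < y_max,
    "score must be in [0,1] or NA" = is.na(score) || (score >= 0 && score <= 1)
  )
  structure(
    list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
         score = as.numeric(score)),
    class = "detection_box"
  )
}

#' Instrument mask
#'
#' One detected or annotated surgical instrument in one frame, carried either
#' as a polygon outline (vertices in pixel coordinates) or as a binary raster
#' of the frame's dimensions. Exactly one of the two representations is
#' present; [polygon_to_raster()] converts.
#'
#' @param label instrument label (e.g. `"forceps"`).
#' @param polygon `n x 2` matrix (or list of points) of polygon vertices,
#'   `n >= 3`; assumed simple (non-self-intersecting).
#' @param raster logical matrix of dimension `height x width` with at least
#'   one `TRUE` pixel.
#' @param confidence optional detector score in `[0, 1]`.
#' @param box optional [detection_box()].
#' @return An `instrument_mask` object.
#' @export
instrument_mask <- function(label, polygon = NULL, raster = NULL,
                            confidence = NA_real_, box = NULL) {
  if (is.null(polygon) == is.null(raster)) {
    stop("exactly one of `polygon` or `raster` must be given")
  }
  if (!is.null(polygon)) {
    polygon <- as_point_matrix(polygon)
    stopifnot(
      "polygon needs >= 3 vertices" = nrow(polygon) >= 3L,
      "polygon vertices must be finite" = all(is.finite(polygon))
    )
  }
  if (!is.null(raster)) {
    stopifnot(
      "raster must be a logical matrix" = is.matrix(raster) && is.logical(raster),
      "raster has no set pixels" = any(raster)
    )
  }
  stopifnot("confidence must be in [0,1] or NA" =
              is.na(confidence) || (confidence >= 0 && confidence <= 1))
  if (!is.null(box)) stopifnot(inherits(box, "detection_box"))
  structure(
    list(label = as.character(label), polygon = polygon, raster = raster,
         confidence = as.numeric(confidence), box = box),
    class = "instrument_mask"
  )
}

#' @export
print.instrument_mask <- function(x, ...) {
  rep <- if (!is.null(x$polygon)) {
    sprintf("polygon (%d vertices)", nrow(x$polygon))
  } else {
    sprintf("raster (%d px)", sum(x$raster))
  }
  cat(sprintf("<instrument_mask> '%s', %s%s\n", x$label, rep,
              if (!is.na(x$confidence)) sprintf(", score %.2f", x$confidence) else ""))
  invisible(x)
}

#' Annotated frame
#'
#' One video frame's instruments plus, when available, the manually
#' annotated true gazing point used as evaluation ground truth.
#'
#' @param frame_index 0-based frame number.
#' @param instruments list of [instrument_mask()] objects.
#' @param spec the [frame_spec()].
#' @param true_gaze optional `c(x, y)` true gaze point.
#' @param timestamp seconds; defaults to `frame_index * spec$frame_interval`.
#' @return An `annotated_frame` object.
#' @export
annotated_frame <- function(frame_index, instruments, spec,
                            true_gaze = NULL, timestamp = NULL) {
  frame_index <- as.integer(frame_index)
  stopifnot(
    "frame_index must be >= 0" = length(frame_index) == 1L && frame_index >= 0L,
    inherits(spec, "frame_spec"),
    is.list(instruments)
  )
  for (m in instruments) stopifnot(inherits(m, "instrument_mask"))
  if (!is.null(true_gaze)) true_gaze <- as_point(true_gaze)
  if (is.null(timestamp)) timestamp <- frame_index * spec$frame_interval
  structure(
    list(frame_index = frame_index, timestamp = timestamp,
         instruments = instruments, true_gaze = true_gaze, spec = spec),
    class = "annotated_frame"
  )
}

#' @export
print.annotated_frame <- function(x, ...) {
  cat(sprintf("<annotated_frame> #%d (t = %.2f s): %d instrument(s)%s\n",
              x$frame_index, x$timestamp, length(x$instruments),
              if (!is.null(x$true_gaze)) {
                sprintf(", true gaze (%.1f, %.1f)", x$true_gaze[1], x$true_gaze[2])
              } else ""))
  invisible(x)
}
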
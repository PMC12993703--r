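#' Read a Labelme polygon annotation file
#'
#' Parses one frame's annotations from Labelme-dialect JSON. Each polygon
#' shape becomes an [instrument_mask()] with its label preserved. A shape
#' carrying the reserved label `"gaze"` (a point shape or a 1-vertex polygon)
#' is not an instrument: its first vertex populates the frame's true gazing
#' point. Non-polygon shapes and polygons with fewer than 3 vertices are
#' skipped with a warning.
#'
#' @param path path to the JSON file.
#' @param spec optional [frame_spec()]; when `NULL`, dimensions are taken
#'   from the file's `imageWidth`/`imageHeight` (frame interval 0.25 s).
#' @param frame_index frame number to stamp on the result (default 0).
#' @return An [annotated_frame()].
#' @export
read_labelme <- function(path, spec = NULL, frame_index = 0L) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed Labelme JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$shapes)) {
    stop("malformed Labelme JSON in '", path, "': missing field 'shapes'",
         call. = FALSE)
  }
  if (is.null(spec)) {
    if (is.null(doc$imageWidth) || is.null(doc$imageHeight)) {
      stop("malformed Labelme JSON in '", path,
           "': missing field 'imageWidth'/'imageHeight' and no frame_spec given",
           call. = FALSE)
    }
    spec <- frame_spec(doc$imageWidth, doc$imageHeight)
  }
  instruments <- list()
  true_gaze <- NULL
  for (shape in doc$shapes) {
    label <- as.character(shape$label %||% "")
    pts <- shape$points
    if (is.null(pts)) {
      stop("malformed Labelme JSON in '", path, "': shape '", label,
           "' missing field 'points'", call. = FALSE)
    }
    pts <- do.call(rbind, lapply(pts, function(p) as.numeric(unlist(p))))
    if (identical(label, "gaze")) {
      true_gaze <- as_point(pts[1, ])
      next
    }
    stype <- shape$shape_type %||% "polygon"
    if (!identical(stype, "polygon") || nrow(pts) < 3L) {
      warning("skipping shape '", label, "' in '", basename(path),
              "': not a polygon with >= 3 points", call. = FALSE)
      next
    }
    instruments[[length(instruments) + 1L]] <- instrument_mask(label, polygon = pts)
  }
  annotated_frame(frame_index, instruments, spec, true_gaze = true_gaze)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Labelme annotation file
#'
#' Inverse of [read_labelme()]: writes the frame's instrument polygons (and
#' the true gaze point under the reserved `"gaze"` label) as Labelme-dialect
#' JSON, so synthetic scenes can round-trip through the same reader used for
#' real annotations.
#'
#' @param frame an [annotated_frame()] whose instruments carry polygons.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(frame, path) {
  stopifnot(inherits(frame, "annotated_frame"))
  shapes <- lapply(frame$instruments, function(m) {
    if (is.null(m$polygon)) stop("instrument '", m$label, "' has no polygon")
    list(label = m$label, shape_type = "polygon",
         points = lapply(seq_len(nrow(m$polygon)),
                         function(i) as.numeric(m$polygon[i, ])))
  })
  if (!is.null(frame$true_gaze)) {
    shapes[[length(shapes) + 1L]] <- list(
      label = "gaze", shape_type = "point",
      points = list(as.numeric(frame$true_gaze)))
  }
  doc <- list(version = "5.0.1", flags = structure(list(), names = character(0)),
              shapes = shapes, imagePath = "",
              imageWidth = frame$spec$width, imageHeight = frame$spec$height)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a binary PNG instrument mask
#'
#' Reads a single-instrument mask image (0/255 or 0/1 grayscale PNG) into a
#' raster-carried [instrument_mask()].
#'
#' @param path PNG path.
#' @param label instrument label to attach.
#' @param threshold pixel values strictly above this (on the 0-1 scale) are
#'   set.
#' @return An [instrument_mask()].
#' @export
read_mask_png <- function(path, label = "instrument", threshold = 0.5) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG masks requires the 'png' package")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  instrument_mask(label, raster = img > threshold)
}

#' Read COCO-style detections
#'
#' Adapter for detector output: a JSON array of records with `image_id`,
#' `bbox` as `[x, y, width, height]` and `score`, the format Mask R-CNN
#' style detectors emit. Boxes are returned in corner form for [ap50()].
#'
#' @param path JSON path.
#' @return data frame with columns `frame_index`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `score`, `label`.
#' @export
read_detections <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(recs, function(r) {
    bb <- as.numeric(unlist(r$bbox))
    if (length(bb) != 4L) stop("detection record missing 4-element 'bbox'")
    data.frame(frame_index = as.integer(r$image_id %||% 0L),
               x_min = bb[1], y_min = bb[2],
               x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
               score = as.numeric(r$score %||% NA_real_),
               label = as.character(r$category_id %||% r$label %||% ""))
  })
  do.call(rbind, rows)
}

## ---- gaze-track CSV ----

track_columns <- c("frame_index", "timestamp", "x", "y", "status",
                   "n_axes", "n_intersections", "n_inliers")

#' Write a gaze track to CSV
#'
#' One row per frame (or per window for smoothed tracks), including frames
#' where no gaze could be estimated (empty `x`,`y` and a non-`ok` status).
#' Header: `frame_index,timestamp,x,y,status,n_axes,n_intersections,n_inliers`.
#' Coordinates are written with 9 decimals so a round trip through
#' [read_gaze_track()] reproduces them to well under 1e-6 px.
#'
#' @param track a `gaze_track` data frame (see [estimate_track()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze_track <- function(track, path) {
  stopifnot(is.data.frame(track), nrow(track) > 0L,
            all(track_columns %in% names(track)))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.9f", v))
  out <- data.frame(
    frame_index = track$frame_index,
    timestamp = sprintf("%.6f", track$timestamp),
    x = fmt(track$x), y = fmt(track$y),
    status = track$status,
    n_axes = track$n_axes, n_intersections = track$n_intersections,
    n_inliers = track$n_inliers,
    stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write gaze track to '", path, "': ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a gaze track CSV
#'
#' @param path CSV written by [write_gaze_track()].
#' @param spec optional [frame_spec()] to attach.
#' @return A `gaze_track` data frame.
#' @export
read_gaze_track <- function(path, spec = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                 colClasses = c(frame_index = "integer", timestamp = "numeric",
                                x = "numeric", y = "numeric", status = "character",
                                n_axes = "integer", n_intersections = "integer",
                                n_inliers = "integer"))
  stopifnot(all(track_columns %in% names(df)))
  new_gaze_track(df, spec = spec)
}

## internal constructor: a gaze track is a data.frame with track_columns and
## attributes frame_spec, method, window (list(n_frames, mode))
new_gaze_track <- function(df, spec = NULL, method = "method1",
                           window = list(n_frames = 1L, mode = "none")) {
  stopifnot(all(track_columns %in% names(df)))
  structure(df[track_columns],
            class = c("gaze_track", "data.frame"),
            row.names = seq_len(nrow(df)),
            frame_spec = spec, method = method, window = window)
}

#' @export
print.gaze_track <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<gaze_track> %d estimate(s), method %s (window %d, %s), %d ok\n",
              nrow(x), attr(x, "method") %||% "?", w$n_frames %||% 1L,
              w$mode %||% "none", sum(x$status == "ok")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}
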
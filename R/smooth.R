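#' Time-averaging window specification
#'
#' At the 0.25-s frame grid, a 4-frame window is the 1-s average (method 2)
#' and a 20-frame window the 5-s average (method 3); 1 frame is the raw
#' per-frame track (method 1). Tumbling windows partition the track into
#' consecutive non-overlapping blocks and emit one estimate per block (how
#' the evaluation integrates frames into one picture); trailing windows are
#' the causal variant for real-time overlay, emitting one estimate per frame
#' from the most recent `n_frames` frames.
#'
#' @param n_frames window length in frames (`>= 1`).
#' @param mode `"tumbling"` or `"trailing"`.
#' @return A `window_spec` object.
#' @export
window_spec <- function(n_frames, mode = c("tumbling", "trailing")) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames <= 0L) stop("n_frames must be >= 1")
  mode <- match.arg(mode)
  structure(list(n_frames = n_frames, mode = mode), class = "window_spec")
}

method_for_window <- function(n_frames) {
  if (n_frames == 1L) "method1" else if (n_frames == 4L) "method2"
  else if (n_frames == 20L) "method3" else sprintf("window%d", n_frames)
}

#' Time-average a gaze track
#'
#' For each window, collects the per-frame gaze points with `ok` status, runs
#' LOF outlier exclusion on them, and emits the centre of gravity of the
#' inliers as the window's gaze estimate. Windows containing no usable point
#' yield `insufficient_instruments`. In tumbling mode a trailing partial
#' window is dropped; in trailing mode early partial windows are emitted and
#' marked in a `partial` column.
#'
#' In the output rows, `n_axes` counts the contributing ok frames,
#' `n_intersections` the candidate points entering LOF and `n_inliers` the
#' points kept.
#'
#' @param track a raw (method 1) `gaze_track` from [estimate_track()].
#' @param window a [window_spec()].
#' @param lof a [lof_params()] for within-window exclusion.
#' @return A `gaze_track` (method set from the window length).
#' @export
smooth_track <- function(track, window = window_spec(4), lof = lof_params()) {
  stopifnot(inherits(track, "gaze_track"), inherits(window, "window_spec"),
            inherits(lof, "lof_params"))
  if (!identical(attr(track, "method"), "method1")) {
    stop("smooth_track expects a raw per-frame (method 1) track")
  }
  n <- nrow(track)
  nf <- window$n_frames

  summarise_window <- function(rows) {
    ok <- rows$status == "ok"
    last <- rows[nrow(rows), ]
    if (!any(ok)) {
      return(data.frame(frame_index = last$frame_index, timestamp = last$timestamp,
                        x = NA_real_, y = NA_real_,
                        status = "insufficient_instruments",
                        n_axes = 0L, n_intersections = 0L, n_inliers = 0L,
                        stringsAsFactors = FALSE))
    }
    pts <- cbind(rows$x[ok], rows$y[ok])
    inlier <- exclude_outliers(pts, lof)
    g <- centroid(pts[inlier, , drop = FALSE])
    data.frame(frame_index = last$frame_index, timestamp = last$timestamp,
               x = g[1], y = g[2], status = "ok",
               n_axes = sum(ok), n_intersections = nrow(pts),
               n_inliers = sum(inlier), stringsAsFactors = FALSE)
  }

  if (window$mode == "tumbling") {
    n_win <- n %/% nf
    if (n_win == 0L) stop("track shorter than one tumbling window")
    rows <- lapply(seq_len(n_win), function(w) {
      summarise_window(track[((w - 1L) * nf + 1L):(w * nf), , drop = FALSE])
    })
    df <- do.call(rbind, rows)
  } else {
    rows <- lapply(seq_len(n), function(i) {
      summarise_window(track[max(1L, i - nf + 1L):i, , drop = FALSE])
    })
    df <- do.call(rbind, rows)
    df$partial <- seq_len(n) < nf
  }
  out <- new_gaze_track(df, spec = attr(track, "frame_spec"),
                        method = method_for_window(nf),
                        window = list(n_frames = nf, mode = window$mode))
  if (window$mode == "trailing") out$partial <- df$partial
  out
}

#' Frame-to-frame dispersion of a gaze track
#'
#' Root-mean-square displacement between consecutive usable (`ok`) estimates:
#' a scalar summary of how much the estimated gaze point fluctuates, the
#' quantity time averaging is meant to suppress.
#'
#' @param track a `gaze_track`.
#' @return RMS displacement in pixels.
#' @export
track_dispersion <- function(track) {
  stopifnot(inherits(track, "gaze_track"))
  ok <- track[track$status == "ok", , drop = FALSE]
  if (nrow(ok) < 2L) stop("track_dispersion needs at least 2 ok estimates")
  dx <- diff(ok$x); dy <- diff(ok$y)
  sqrt(mean(dx^2 + dy^2))
}
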
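#' Intersection over union of two boxes
#'
#' `area(P intersect GT) / area(P union GT)` with areas in continuous px^2;
#' 0 when the boxes are disjoint.
#'
#' @param p,gt [detection_box()] objects (or lists with the same fields).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(p, gt) {
  for (b in list(p, gt)) {
    if (!(b$x_min < b$x_max && b$y_min < b$y_max)) stop("degenerate box")
  }
  ix <- max(0, min(p$x_max, gt$x_max) - max(p$x_min, gt$x_min))
  iy <- max(0, min(p$y_max, gt$y_max) - max(p$y_min, gt$y_min))
  inter <- ix * iy
  area_p <- (p$x_max - p$x_min) * (p$y_max - p$y_min)
  area_g <- (gt$x_max - gt$x_min) * (gt$y_max - gt$y_min)
  inter / (area_p + area_g - inter)
}

#' Average precision at IoU 0.5 (AP50)
#'
#' Standard detection evaluation: predictions are sorted by descending
#' confidence and matched greedily, one-to-one and per frame, to the
#' unmatched ground-truth box of highest IoU; a match with IoU >= 0.5 is a
#' true positive. AP is the area under the all-point interpolated
#' precision-recall curve. Because "detection rate at AP50" is sometimes read
#' as recall at IoU 0.5, the report also carries `recall_at_50`.
#'
#' @param predictions data frame with columns `frame_index`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, `score`.
#' @param ground_truth data frame with columns `frame_index`, `x_min`,
#'   `y_min`, `x_max`, `y_max`.
#' @param iou_threshold correctness threshold (default 0.5).
#' @return A `detection_eval_report`: `n_gt`, `n_pred`, `ap50`,
#'   `recall_at_50`, and `curve`, the per-rank precision-recall table.
#' @export
ap50 <- function(predictions, ground_truth, iou_threshold = 0.5) {
  gt_cols <- c("frame_index", "x_min", "y_min", "x_max", "y_max")
  stopifnot(is.data.frame(ground_truth), all(gt_cols %in% names(ground_truth)))
  if (nrow(ground_truth) == 0L) stop("ap50: empty ground truth")
  n_gt <- nrow(ground_truth)

  if (is.null(predictions) || nrow(predictions) == 0L) {
    return(structure(list(n_gt = n_gt, n_pred = 0L, ap50 = 0,
                          recall_at_50 = 0, curve = NULL),
                     class = "detection_eval_report"))
  }
  stopifnot(all(c(gt_cols, "score") %in% names(predictions)))
  n_pred <- nrow(predictions)
  ord <- order(predictions$score, decreasing = TRUE)
  preds <- predictions[ord, , drop = FALSE]

  gt_used <- rep(FALSE, n_gt)
  tp <- logical(n_pred)
  for (i in seq_len(n_pred)) {
    cand <- which(!gt_used & ground_truth$frame_index == preds$frame_index[i])
    if (!length(cand)) next
    ious <- vapply(cand, function(j) {
      box_iou(preds[i, ], ground_truth[j, ])
    }, numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      gt_used[cand[best]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_len(n_pred)
  recall <- cum_tp / n_gt

  ## all-point interpolation: integrate max-precision-to-the-right over recall
  p_interp <- rev(cummax(rev(precision)))
  rec_prev <- c(0, recall[-n_pred])
  ap <- sum((recall - rec_prev) * p_interp)

  structure(
    list(n_gt = n_gt, n_pred = n_pred, ap50 = ap,
         recall_at_50 = recall[n_pred],
         curve = data.frame(score = preds$score, tp = tp,
                            precision = precision, recall = recall)),
    class = "detection_eval_report"
  )
}

#' @export
print.detection_eval_report <- function(x, ...) {
  cat(sprintf("<detection_eval_report> %d GT, %d predictions: AP50 = %.3f, recall@0.5 = %.3f\n",
              x$n_gt, x$n_pred, x$ap50, x$recall_at_50))
  invisible(x)
}

#' Correct-circle radial accuracy of a gaze track
#'
#' An estimate is a hit at radius `r` when its Euclidean distance to the true
#' gazing point is at most `r` (boundary inclusive). Frames whose estimate
#' has a non-`ok` status count as misses at every radius unless
#' `skip_missing = TRUE`. Truth frames are matched to track rows by frame
#' index; for tumbling-window tracks a truth frame is matched to the window
#' that covers it, and truth frames not covered by any emitted window are
#' excluded (reported in `n_unmatched`).
#'
#' @param track a `gaze_track`.
#' @param truth data frame with columns `frame_index`, `x`, `y` — the true
#'   gaze annotations.
#' @param radii correct-circle radii in px (default the 108..540 ladder).
#' @param skip_missing drop non-`ok` frames from the denominator instead of
#'   scoring them as misses.
#' @return A `radial_accuracy_report`: `radii`, `hits`, `n_evaluated`,
#'   `n_unmatched`, `accuracy`, and `distances` (per evaluated frame; `NA`
#'   for non-`ok` frames).
#' @export
radial_accuracy <- function(track, truth,
                            radii = c(108, 216, 324, 432, 540),
                            skip_missing = FALSE) {
  stopifnot(is.data.frame(track), all(c("frame_index", "x", "y", "status") %in% names(track)),
            is.data.frame(truth), all(c("frame_index", "x", "y") %in% names(truth)),
            length(radii) >= 1L, all(radii > 0))
  radii <- sort(radii)
  win <- attr(track, "window") %||% list(n_frames = 1L, mode = "none")
  nf <- win$n_frames %||% 1L

  match_row <- function(fi) {
    if (identical(win$mode, "tumbling") && nf > 1L) {
      hit <- which(track$frame_index - nf + 1L <= fi & fi <= track$frame_index)
    } else {
      hit <- which(track$frame_index == fi)
    }
    if (length(hit)) hit[1L] else NA_integer_
  }
  rows <- vapply(truth$frame_index, match_row, integer(1))
  n_unmatched <- sum(is.na(rows))
  keep <- !is.na(rows)
  if (!any(keep)) stop("radial_accuracy: no truth frame matches the track")
  t_keep <- truth[keep, , drop = FALSE]
  r_keep <- track[rows[keep], , drop = FALSE]

  dist <- sqrt((r_keep$x - t_keep$x)^2 + (r_keep$y - t_keep$y)^2)
  ok <- r_keep$status == "ok"
  dist[!ok] <- NA_real_
  if (skip_missing) {
    eval_idx <- ok
  } else {
    eval_idx <- rep(TRUE, length(dist))
  }
  n_eval <- sum(eval_idx)
  if (n_eval == 0L) stop("radial_accuracy: no evaluable frames")
  d_eval <- dist[eval_idx]
  hits <- vapply(radii, function(r) sum(!is.na(d_eval) & d_eval <= r), integer(1))

  structure(
    list(radii = radii, hits = hits, n_evaluated = n_eval,
         n_unmatched = n_unmatched, accuracy = hits / n_eval,
         distances = dist),
    class = "radial_accuracy_report"
  )
}

#' @export
print.radial_accuracy_report <- function(x, ...) {
  cat(sprintf("<radial_accuracy_report> %d frame(s) evaluated (%d truth frames unmatched)\n",
              x$n_evaluated, x$n_unmatched))
  for (i in seq_along(x$radii)) {
    cat(sprintf("  r = %4g px: %3d/%d  accuracy %.3f\n",
                x$radii[i], x$hits[i], x$n_evaluated, x$accuracy[i]))
  }
  invisible(x)
}

#' Screen-area fraction of a correct circle
#'
#' The area of the radius-`r` disc as a percentage of the frame area (no
#' clipping at frame borders): `100 * pi * r^2 / (width * height)`. Useful
#' for judging how demanding a correct-circle radius is; at 1440x1080, the
#' 216-px circle covers 9.42% of the screen and the 324-px circle 21.2%.
#'
#' @param r radius in px.
#' @param spec the [frame_spec()].
#' @return Percentage of the screen area.
#' @examples
#' circle_area_fraction(216, frame_spec(1440, 1080))
#' @export
circle_area_fraction <- function(r, spec) {
  stopifnot(r > 0, inherits(spec, "frame_spec"))
  100 * pi * r^2 / (spec$width * spec$height)
}
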
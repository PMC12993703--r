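#' Read a pipeline configuration file
#'
#' YAML with optional sections `axis`, `intersect`, `lof`, `smooth`,
#' `evaluate`, `simulate`, plus global keys `seed` and `log_level`. Unknown
#' keys are rejected with the offending section named, so a typo never
#' silently falls back to a default.
#'
#' @param path YAML path; `NULL` returns the defaults.
#' @return List with `config` (a [gaze_config()]), `smooth` (`n_frames`,
#'   `mode`), `evaluate` (`radii`, `skip_missing`), `simulate` (passed to
#'   [scene_params()]), `seed`, `log_level`.
#' @export
read_run_config <- function(path = NULL) {
  known <- list(
    axis = c("min_elongation", "min_area"),
    intersect = c("min_angle", "max_distance_factor"),
    lof = c("n_neighbors", "contamination", "min_points_for_lof"),
    smooth = c("n_frames", "mode"),
    evaluate = c("radii", "skip_missing"),
    simulate = c("width", "height", "frame_interval", "n_instruments",
                 "instrument_length", "instrument_width", "axis_offset_sigma",
                 "angle_jitter_sigma", "p_distractor", "distractor_offset",
                 "p_miss")
  )
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad_top <- setdiff(names(raw), c(names(known), "seed", "log_level"))
  if (length(bad_top)) {
    stop("unknown config section(s): ", paste(bad_top, collapse = ", "))
  }
  for (sec in intersect(names(raw), names(known))) {
    bad <- setdiff(names(raw[[sec]]), known[[sec]])
    if (length(bad)) {
      stop("unknown key(s) in section [", sec, "]: ",
           paste(bad, collapse = ", "))
    }
  }
  lof_args <- raw$lof %||% list()
  cfg <- gaze_config(
    axis = raw$axis %||% list(),
    intersect = raw$intersect %||% list(),
    lof = do.call(lof_params, lof_args)
  )
  list(
    config = cfg,
    smooth = utils::modifyList(list(n_frames = 1L, mode = "tumbling"),
                               raw$smooth %||% list()),
    evaluate = utils::modifyList(
      list(radii = c(108, 216, 324, 432, 540), skip_missing = FALSE),
      raw$evaluate %||% list()),
    simulate = raw$simulate %||% list(),
    seed = raw$seed %||% NULL,
    log_level = raw$log_level %||% "info"
  )
}

#' Run the full gaze pipeline over a directory of annotations
#'
#' Reads every Labelme `*.json` annotation in `frames_dir` in lexicographic
#' order (frame indices assigned in that order), estimates the per-frame gaze
#' track, optionally time-averages it, writes the track CSV and — when the
#' annotations carry `"gaze"` ground-truth points — a radial-accuracy report
#' JSON. Deterministic: the estimation path draws no random numbers.
#'
#' @param frames_dir directory of per-frame Labelme JSON files.
#' @param out_dir output directory (created if needed).
#' @param config a [gaze_config()].
#' @param n_frames_window window length: 1 = method 1 (raw), 4 = method 2,
#'   20 = method 3.
#' @param mode window mode for `n_frames_window > 1`.
#' @param radii correct-circle radii for the evaluation report.
#' @param skip_missing see [radial_accuracy()].
#' @return List with `track`, `report` (or `NULL`), `track_path`,
#'   `report_path`.
#' @export
run_pipeline <- function(frames_dir, out_dir, config = gaze_config(),
                         n_frames_window = 1L, mode = "tumbling",
                         radii = c(108, 216, 324, 432, 540),
                         skip_missing = FALSE) {
  if (!dir.exists(frames_dir)) stop("frames_dir does not exist: ", frames_dir)
  files <- sort(list.files(frames_dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) stop("no .json annotation files in ", frames_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  frames <- lapply(seq_along(files), function(i) {
    read_labelme(files[i], frame_index = i - 1L)
  })
  dims <- vapply(frames, function(f) c(f$spec$width, f$spec$height), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("mixed frame resolutions across annotation files")
  }

  track <- estimate_track(frames, config)
  if (n_frames_window > 1L) {
    track <- smooth_track(track, window_spec(n_frames_window, mode),
                          lof = config$lof)
  }
  track_path <- file.path(out_dir, "track.csv")
  write_gaze_track(track, track_path)

  report <- NULL
  report_path <- NULL
  has_truth <- vapply(frames, function(f) !is.null(f$true_gaze), logical(1))
  if (any(has_truth)) {
    truth <- do.call(rbind, lapply(frames[has_truth], function(f) {
      data.frame(frame_index = f$frame_index,
                 x = f$true_gaze[1], y = f$true_gaze[2])
    }))
    report <- radial_accuracy(track, truth, radii = radii,
                              skip_missing = skip_missing)
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(radii = report$radii, hits = report$hits,
           n_evaluated = report$n_evaluated, n_unmatched = report$n_unmatched,
           accuracy = report$accuracy),
      report_path, auto_unbox = FALSE, digits = NA)
  }
  list(track = track, report = report,
       track_path = track_path, report_path = report_path)
}
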
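#' Synthetic scene parameters
#'
#' Controls the generator that emulates the structure of open-surgery video
#' frames: 2-5 elongated instruments entering from the frame border and
#' converging on the operative field, where the surgeon's gaze sits. Each
#' instrument is rendered as a capsule (rectangle with semicircular ends, the
#' smooth-tipped silhouette of forceps and energy devices) whose long axis
#' aims at the true gaze point up to a perpendicular offset and an angular
#' jitter; occasional "distractor" instruments aim well away from the gaze,
#' emulating idle or retracting tools.
#'
#' @param spec the [frame_spec()] (default 1440x1080 at 0.25 s).
#' @param n_instruments integer range `c(min, max)` of instruments per frame.
#' @param instrument_length,instrument_width capsule size ranges in px.
#' @param axis_offset_sigma SD (px) of the perpendicular miss distance of an
#'   instrument's axis from the true gaze; draws are clamped at 3 sigma so a
#'   non-distractor axis never passes farther than `3 * axis_offset_sigma`
#'   from the gaze.
#' @param angle_jitter_sigma SD (degrees) of the axis rotation about its aim
#'   point.
#' @param p_distractor per-instrument probability of being a distractor.
#' @param distractor_offset minimum distance (px) of a distractor's aim point
#'   from the true gaze.
#' @param p_miss per-instrument, per-frame probability that the detector
#'   missed the instrument (mask dropped from the frame); the sole
#'   detector-failure proxy.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A `scene_params` object.
#' @export
scene_params <- function(spec = frame_spec(1440, 1080),
                         n_instruments = c(2L, 5L),
                         instrument_length = c(300, 700),
                         instrument_width = c(20, 60),
                         axis_offset_sigma = 15,
                         angle_jitter_sigma = 3,
                         p_distractor = 0.1,
                         distractor_offset = 500,
                         p_miss = 0,
                         seed = NULL) {
  stopifnot(
    inherits(spec, "frame_spec"),
    length(n_instruments) == 2L, n_instruments[1] >= 1L,
    n_instruments[2] >= n_instruments[1],
    all(instrument_length > 0), all(instrument_width > 0),
    instrument_length[2] >= instrument_length[1],
    instrument_width[2] >= instrument_width[1],
    axis_offset_sigma >= 0, angle_jitter_sigma >= 0,
    p_distractor >= 0, p_distractor <= 1,
    p_miss >= 0, p_miss <= 1,
    distractor_offset > 0
  )
  if (instrument_length[2] > frame_diagonal(spec)) {
    stop("instrument_length exceeds the frame diagonal: impossible geometry")
  }
  structure(
    list(spec = spec, n_instruments = as.integer(n_instruments),
         instrument_length = instrument_length,
         instrument_width = instrument_width,
         axis_offset_sigma = axis_offset_sigma,
         angle_jitter_sigma = angle_jitter_sigma,
         p_distractor = p_distractor, distractor_offset = distractor_offset,
         p_miss = p_miss, seed = seed),
    class = "scene_params"
  )
}

## minimum angular separation (degrees) between instrument approach
## directions: tools held by different hands/assistants come from distinct
## directions, and it keeps axis pairs away from the near-parallel regime
MIN_APPROACH_SEP_DEG <- 15

## run `expr` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

draw_subseed <- function() sample.int(.Machine$integer.max, 1L)

## capsule outline: rectangle base->tip of given width with semicircular caps
capsule_polygon <- function(base, tip, width, n_cap = 10L) {
  d <- tip - base
  len <- sqrt(sum(d^2))
  stopifnot("capsule needs distinct base and tip" = len > 0)
  d <- d / len
  nv <- c(-d[2], d[1])
  r <- width / 2
  t1 <- seq(0, pi, length.out = n_cap)        # cap around the tip
  t2 <- seq(pi, 2 * pi, length.out = n_cap)   # cap around the base
  tip_arc <- cbind(tip[1] + r * (cos(t1) * nv[1] + sin(t1) * d[1]),
                   tip[2] + r * (cos(t1) * nv[2] + sin(t1) * d[2]))
  base_arc <- cbind(base[1] + r * (cos(t2) * nv[1] + sin(t2) * d[1]),
                    base[2] + r * (cos(t2) * nv[2] + sin(t2) * d[2]))
  rbind(tip_arc, base_arc)
}

## uniform point in the central 60% of the frame
sample_central_gaze <- function(spec) {
  c(runif(1, 0.2 * spec$width, 0.8 * spec$width),
    runif(1, 0.2 * spec$height, 0.8 * spec$height))
}

## where the ray from p in direction angle phi exits the frame rectangle
border_exit <- function(p, phi, spec) {
  u <- c(cos(phi), sin(phi))
  tx <- if (u[1] > 0) (spec$width - p[1]) / u[1] else if (u[1] < 0) -p[1] / u[1] else Inf
  ty <- if (u[2] > 0) (spec$height - p[2]) / u[2] else if (u[2] < 0) -p[2] / u[2] else Inf
  p + min(tx, ty) * u
}

## separation of two approach directions as *axis* directions (mod 180):
## tools facing each other from opposite borders have collinear axes, which
## is just as degenerate for intersection as a parallel pair
circular_sep_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

## persistent (across a sequence) properties of one instrument; draws from
## the current RNG stream; rejection only consults *earlier* instruments
sample_instrument_static <- function(params, prev_angles_deg) {
  is_distractor <- runif(1) < params$p_distractor
  phi_deg <- NA_real_
  for (try in seq_len(100L)) {
    cand <- runif(1, 0, 360)
    if (!length(prev_angles_deg) ||
        all(circular_sep_deg(cand, prev_angles_deg) >= MIN_APPROACH_SEP_DEG)) {
      phi_deg <- cand
      break
    }
  }
  if (is.na(phi_deg)) phi_deg <- runif(1, 0, 360)  # crowded frame: accept anyway
  list(
    is_distractor = is_distractor,
    phi_deg = phi_deg,
    length = runif(1, params$instrument_length[1], params$instrument_length[2]),
    width = runif(1, params$instrument_width[1], params$instrument_width[2]),
    distractor_dir = runif(1, 0, 2 * pi),
    distractor_mag = runif(1, 1, 1.3) * params$distractor_offset
  )
}

## per-frame realization: noise draws from the current RNG stream, then
## capsule construction around the aim point
realize_instrument <- function(static, gaze, params, index) {
  spec <- params$spec
  missed <- runif(1) < params$p_miss
  delta <- rnorm(1, 0, params$axis_offset_sigma)
  delta <- max(-3 * params$axis_offset_sigma,
               min(3 * params$axis_offset_sigma, delta))
  theta <- rnorm(1, 0, params$angle_jitter_sigma) * pi / 180
  gap <- runif(1, 40, 140)

  phi <- static$phi_deg * pi / 180
  entry <- border_exit(gaze, phi, spec)

  if (static$is_distractor) {
    aim <- NULL
    dir_try <- static$distractor_dir
    for (try in seq_len(50L)) {
      cand <- gaze + static$distractor_mag * c(cos(dir_try), sin(dir_try))
      if (cand[1] > 20 && cand[1] < spec$width - 20 &&
          cand[2] > 20 && cand[2] < spec$height - 20) {
        aim <- cand
        break
      }
      dir_try <- runif(1, 0, 2 * pi)
    }
    if (is.null(aim)) {  # extreme params: clamp the aim into the frame
      cand <- gaze + static$distractor_mag * c(cos(static$distractor_dir),
                                               sin(static$distractor_dir))
      aim <- pmin(pmax(cand, 20), c(spec$width, spec$height) - 20)
    }
  } else {
    n_perp <- c(-sin(phi), cos(phi))
    aim <- gaze + delta * n_perp
  }

  d0 <- aim - entry
  reach <- sqrt(sum(d0^2))
  d0 <- d0 / reach
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  d <- as.numeric(rot %*% d0)
  ## jitter rotates about the aim point: the axis still passes through it
  gap <- min(gap, 0.3 * reach)  # always leave room for the shaft
  tip <- aim - gap * d
  ## shorten the shaft so the whole capsule stays inside the frame: a
  ## border-clipped mask loses its symmetry and its moment axis would no
  ## longer be the true centreline
  margin <- static$width / 2 + 2
  u <- -d
  tx <- if (u[1] > 0) (spec$width - margin - tip[1]) / u[1]
        else if (u[1] < 0) (margin - tip[1]) / u[1] else Inf
  ty <- if (u[2] > 0) (spec$height - margin - tip[2]) / u[2]
        else if (u[2] < 0) (margin - tip[2]) / u[2] else Inf
  len <- min(static$length, tx, ty)
  len <- max(len, 2.5 * static$width)  # keep the shape elongated regardless
  base <- tip - len * d

  list(
    mask = if (missed) NULL else instrument_mask(
      sprintf("instrument_%d%s", index,
              if (static$is_distractor) "_distractor" else ""),
      polygon = capsule_polygon(base, tip, static$width)),
    truth = list(is_distractor = static$is_distractor, axis_point = aim,
                 direction = d, tip = tip, base = base,
                 length = static$length, width = static$width,
                 missed = missed)
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  nd <- sum(vapply(x$truth, `[[`, logical(1), "is_distractor"))
  cat(sprintf("<synthetic_scene> #%d: %d instrument(s) (%d distractor), true gaze (%.1f, %.1f)\n",
              x$frame$frame_index, length(x$truth), nd,
              x$frame$true_gaze[1], x$frame$true_gaze[2]))
  invisible(x)
}

#' Generate one synthetic frame
#'
#' Samples a true gaze point uniformly in the central 60% of the frame, then
#' places each instrument on an approach direction from the frame border
#' (approach directions at least 15 degrees apart), aims its axis at the gaze
#' point plus a clamped Gaussian perpendicular offset and a Gaussian angular
#' jitter applied about the aim point, and renders the capsule outline as the
#' instrument's polygon mask. Distractor instruments aim at a point at least
#' `distractor_offset` px from the gaze instead. Deterministic given the
#' seed; each instrument draws from its own substream, so raising
#' `n_instruments` does not perturb the earlier instruments.
#'
#' @param params a [scene_params()].
#' @param seed overrides `params$seed` when given.
#' @param frame_index frame number for the generated frame.
#' @param render_raster also rasterize each mask (off by default: a full
#'   1440x1080 raster is ~6 MB per instrument, and the estimation pipeline
#'   rasterizes on demand).
#' @return A `synthetic_scene`: `$frame` (an [annotated_frame()] with
#'   `true_gaze` set), `$params_used`, and `$truth`, the per-instrument
#'   ground-truth axes and distractor flags.
#' @export
generate_scene <- function(params = scene_params(), seed = params$seed,
                           frame_index = 0L, render_raster = FALSE) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(seed, {
    gaze <- sample_central_gaze(params$spec)
    n <- if (params$n_instruments[1] == params$n_instruments[2]) {
      params$n_instruments[1]
    } else {
      sample(params$n_instruments[1]:params$n_instruments[2], 1L)
    }
    inst_seeds <- vapply(seq_len(n), function(i) draw_subseed(), integer(1))
    statics <- vector("list", n)
    angles <- numeric(0)
    for (i in seq_len(n)) {
      statics[[i]] <- with_seed(inst_seeds[i],
                                sample_instrument_static(params, angles))
      angles <- c(angles, statics[[i]]$phi_deg)
    }
    ## per-frame noise from per-instrument substreams too
    noise_seeds <- vapply(seq_len(n), function(i) draw_subseed(), integer(1))
    realized <- vector("list", n)
    for (i in seq_len(n)) {
      realized[[i]] <- with_seed(noise_seeds[i],
                                 realize_instrument(statics[[i]], gaze,
                                                    params, i))
    }
    masks <- Filter(Negate(is.null), lapply(realized, `[[`, "mask"))
    if (render_raster) masks <- lapply(masks, polygon_to_raster, spec = params$spec)
    structure(
      list(frame = annotated_frame(frame_index, masks, params$spec,
                                   true_gaze = gaze),
           params_used = params,
           truth = lapply(realized, `[[`, "truth")),
      class = "synthetic_scene")
  })
}

#' Generate a synthetic frame sequence
#'
#' The true gaze follows a reflected Gaussian random walk inside the central
#' region; instrument identity is temporally coherent (approach direction,
#' size and distractor status persist across frames) while the per-frame
#' noise (axis offset, angular jitter, tip position, detector misses) is
#' drawn independently each frame.
#'
#' @param params a [scene_params()].
#' @param n_frames number of frames (`>= 1`).
#' @param drift_sigma per-frame SD (px) of the gaze random walk (0 = static
#'   gaze).
#' @param seed overrides `params$seed` when given.
#' @param render_raster as in [generate_scene()].
#' @return List of `synthetic_scene`, frame indices `0:(n_frames-1)`.
#' @export
generate_sequence <- function(params = scene_params(), n_frames,
                              drift_sigma = 0, seed = params$seed,
                              render_raster = FALSE) {
  stopifnot(inherits(params, "scene_params"), n_frames >= 1L, drift_sigma >= 0)
  n_frames <- as.integer(n_frames)
  spec <- params$spec
  with_seed(seed, {
    g <- sample_central_gaze(spec)
    gazes <- matrix(NA_real_, n_frames, 2L)
    gazes[1L, ] <- g
    if (n_frames > 1L) {
      for (t in 2:n_frames) {
        g <- g + rnorm(2L, 0, drift_sigma)
        g[1] <- reflect_into(g[1], 0.2 * spec$width, 0.8 * spec$width)
        g[2] <- reflect_into(g[2], 0.2 * spec$height, 0.8 * spec$height)
        gazes[t, ] <- g
      }
    }
    n <- if (params$n_instruments[1] == params$n_instruments[2]) {
      params$n_instruments[1]
    } else {
      sample(params$n_instruments[1]:params$n_instruments[2], 1L)
    }
    inst_seeds <- vapply(seq_len(n), function(i) draw_subseed(), integer(1))
    statics <- vector("list", n)
    angles <- numeric(0)
    for (i in seq_len(n)) {
      statics[[i]] <- with_seed(inst_seeds[i],
                                sample_instrument_static(params, angles))
      angles <- c(angles, statics[[i]]$phi_deg)
    }
    frame_seeds <- matrix(
      vapply(seq_len(n * n_frames), function(i) draw_subseed(), integer(1)),
      nrow = n_frames, ncol = n, byrow = TRUE)

    lapply(seq_len(n_frames), function(t) {
      realized <- vector("list", n)
      for (i in seq_len(n)) {
        realized[[i]] <- with_seed(frame_seeds[t, i],
                                   realize_instrument(statics[[i]],
                                                      gazes[t, ], params, i))
      }
      masks <- Filter(Negate(is.null), lapply(realized, `[[`, "mask"))
      if (render_raster) masks <- lapply(masks, polygon_to_raster, spec = spec)
      structure(
        list(frame = annotated_frame(t - 1L, masks, spec,
                                     true_gaze = gazes[t, ]),
             params_used = params,
             truth = lapply(realized, `[[`, "truth")),
        class = "synthetic_scene")
    })
  })
}

## reflect a scalar into [lo, hi] (fold at the boundaries)
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  if (y > span) y <- 2 * span - y
  lo + y
}

#' Write a synthetic scene to disk
#'
#' Writes the scene as a Labelme JSON annotation (instruments as polygon
#' shapes, true gaze under the reserved `"gaze"` label) and, optionally, one
#' binary PNG mask per instrument — the same formats the pipeline reads for
#' real data.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem (default `frame_<index>`).
#' @param write_png also write per-instrument PNG masks (requires the `png`
#'   package).
#' @return The JSON path, invisibly.
#' @export
write_scene <- function(scene, dir, stem = NULL, write_png = FALSE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) stem <- sprintf("frame_%05d", scene$frame$frame_index)
  json_path <- file.path(dir, paste0(stem, ".json"))
  write_labelme(scene$frame, json_path)
  if (write_png) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG masks requires the 'png' package")
    }
    for (i in seq_along(scene$frame$instruments)) {
      m <- polygon_to_raster(scene$frame$instruments[[i]], scene$frame$spec)
      png::writePNG(m$raster * 1,
                    file.path(dir, sprintf("%s_mask%02d.png", stem, i)))
    }
  }
  invisible(json_path)
}
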
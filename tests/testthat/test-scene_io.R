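test_that("read_labelme maps polygon shapes to instruments and keeps labels", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_labelme_fixture(path, list(
    list(label = "forceps", shape_type = "polygon",
         points = rbind(c(10, 10), c(60, 10), c(60, 20), c(10, 20))),
    list(label = "scalpel", shape_type = "polygon",
         points = rbind(c(5, 30), c(70, 30), c(70, 36), c(5, 36)))
  ))
  frame <- read_labelme(path)
  expect_s3_class(frame, "annotated_frame")
  expect_length(frame$instruments, 2L)
  expect_equal(vapply(frame$instruments, `[[`, character(1), "label"),
               c("forceps", "scalpel"))
  expect_equal(frame$spec$width, 100L)
  expect_equal(frame$spec$height, 80L)
  expect_null(frame$true_gaze)
})

test_that("read_labelme handles zero shapes and the reserved gaze label", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  writeLines('{"shapes": [], "imageWidth": 100, "imageHeight": 80}', path)
  frame <- read_labelme(path)
  expect_length(frame$instruments, 0L)

  write_labelme_fixture(path, list(
    list(label = "gaze", shape_type = "point",
         points = rbind(c(42.5, 17.25))),
    list(label = "forceps", shape_type = "polygon",
         points = rbind(c(10, 10), c(60, 10), c(60, 20), c(10, 20)))
  ))
  frame <- read_labelme(path)
  expect_length(frame$instruments, 1L)
  expect_equal(frame$true_gaze, c(42.5, 17.25))
})

test_that("read_labelme skips non-polygon shapes with a warning", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_labelme_fixture(path, list(
    list(label = "cable", shape_type = "line",
         points = rbind(c(0, 0), c(10, 10)))
  ))
  expect_warning(frame <- read_labelme(path), "not a polygon")
  expect_length(frame$instruments, 0L)
})

test_that("read_labelme errors name the offending field", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  writeLines("{not json", path)
  expect_error(read_labelme(path), "malformed Labelme JSON")

  writeLines('{"imageWidth": 100, "imageHeight": 80}', path)
  expect_error(read_labelme(path), "shapes")

  writeLines('{"shapes": [{"label": "x", "shape_type": "polygon"}], "imageWidth": 10, "imageHeight": 10}',
             path)
  expect_error(read_labelme(path), "points")

  writeLines('{"shapes": []}', path)
  expect_error(read_labelme(path), "imageWidth")
  expect_length(read_labelme(path, spec = frame_spec(10, 10))$instruments, 0L)
})

test_that("labelme files round-trip through write_labelme", {
  spec <- frame_spec(200, 150)
  poly <- rbind(c(10.25, 20.5), c(90, 22), c(88, 40.75), c(12, 38))
  frame <- annotated_frame(3L, list(instrument_mask("forceps", polygon = poly)),
                           spec, true_gaze = c(55.5, 31.25))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_labelme(frame, path)
  back <- read_labelme(path, frame_index = 3L)
  expect_equal(back$instruments[[1]]$polygon, poly, tolerance = 1e-12)
  expect_equal(back$instruments[[1]]$label, "forceps")
  expect_equal(back$true_gaze, c(55.5, 31.25))
  expect_equal(back$spec$width, 200L)
})

test_that("instrument_mask requires exactly one representation", {
  expect_error(instrument_mask("x"), "exactly one")
  poly <- rbind(c(0, 0), c(1, 0), c(1, 1))
  rast <- matrix(c(TRUE, FALSE), 1, 2)
  expect_error(instrument_mask("x", polygon = poly, raster = rast), "exactly one")
  expect_error(instrument_mask("x", polygon = rbind(c(0, 0), c(1, 1))), ">= 3")
  expect_error(instrument_mask("x", raster = matrix(FALSE, 2, 2)), "no set pixels")
})

test_that("polygon_to_raster sets exactly the pixels whose centres are inside", {
  spec <- frame_spec(100, 100)
  ## axis-aligned rectangle (10,10)-(20,14): 10 x 4 pixel centres = 40
  m <- instrument_mask("r", polygon = rect_polygon(10, 10, 20, 14))
  r <- polygon_to_raster(m, spec)
  expect_equal(sum(r$raster), 40L)
  expect_false(is.null(r$polygon))  # polygon retained

  ## full-frame rectangle covers everything
  full <- polygon_to_raster(
    instrument_mask("f", polygon = rect_polygon(0, 0, 100, 100)), spec)
  expect_equal(sum(full$raster), 100L * 100L)

  ## degenerate (zero-area) triangle covers no centres
  degen <- instrument_mask("d", polygon = rbind(c(1, 1), c(5, 5), c(9, 9)))
  expect_error(polygon_to_raster(degen, spec), "degenerate mask")
  out <- instrument_mask("o", polygon = rect_polygon(-30, -30, -10, -10))
  expect_error(polygon_to_raster(out, spec), "degenerate mask")
})

test_that("rasterization matches the brute-force point-in-polygon oracle", {
  spec <- frame_spec(40, 30)
  set.seed(71)
  polys <- list(
    rect_polygon(3.2, 4.7, 17.9, 11.3),
    rotated_rect(c(20, 15), 22, 6, 30),
    ## non-convex chevron exercises the general scanline path
    rbind(c(5, 5), c(35, 5), c(35, 25), c(20, 12), c(5, 25))
  )
  for (poly in polys) {
    m <- polygon_to_raster(instrument_mask("p", polygon = poly), spec)
    expect_equal(sum(m$raster), brute_raster_count(poly, 40, 30))
  }
})

test_that("raster area tracks the analytic polygon area for convex shapes", {
  spec <- frame_spec(200, 200)
  set.seed(5)
  for (i in 1:5) {
    ctr <- c(runif(1, 60, 140), runif(1, 60, 140))
    len <- runif(1, 40, 90); wid <- runif(1, 12, 30)
    poly <- rotated_rect(ctr, len, wid, runif(1, 0, 180))
    m <- polygon_to_raster(instrument_mask("p", polygon = poly), spec)
    perim <- 2 * (len + wid)
    expect_lt(abs(sum(m$raster) - polygon_area(poly)), perim)
  }
})

test_that("gaze-track CSV round-trips coordinates to 1e-6 px", {
  df <- data.frame(
    frame_index = 0:2,
    timestamp = c(0, 0.25, 0.5),
    x = c(123.456789123, NA, 0.000000123),
    y = c(987.654321987, NA, 1079.999999),
    status = c("ok", "insufficient_instruments", "ok"),
    n_axes = c(3L, 1L, 2L),
    n_intersections = c(3L, 0L, 1L),
    n_inliers = c(3L, 0L, 1L),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_gaze_track(df, path)
  lines <- readLines(path)
  expect_equal(lines[1],
               "frame_index,timestamp,x,y,status,n_axes,n_intersections,n_inliers")
  expect_length(lines, 4L)  # header + one row per frame, missing frames kept
  expect_match(lines[3], ",,,insufficient_instruments")  # empty x,y

  back <- read_gaze_track(path)
  expect_s3_class(back, "gaze_track")
  expect_equal(back$x[c(1, 3)], df$x[c(1, 3)], tolerance = 1e-6)
  expect_equal(back$y[c(1, 3)], df$y[c(1, 3)], tolerance = 1e-6)
  expect_true(is.na(back$x[2]) && is.na(back$y[2]))
  expect_equal(back$status, df$status)
  expect_equal(back$n_axes, df$n_axes)
})

test_that("write_gaze_track reports unwritable paths", {
  df <- data.frame(frame_index = 0L, timestamp = 0, x = 1, y = 2,
                   status = "ok", n_axes = 2L, n_intersections = 1L,
                   n_inliers = 1L, stringsAsFactors = FALSE)
  expect_error(
    suppressWarnings(write_gaze_track(df, file.path(tempdir(), "no/such/dir/x.csv"))),
    "cannot write")
})

test_that("read_detections converts COCO xywh boxes to corner form", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  writeLines(paste0(
    '[{"image_id": 0, "bbox": [10, 20, 30, 40], "score": 0.9, "category_id": 1},',
    ' {"image_id": 1, "bbox": [0, 0, 5, 5], "score": 0.4, "category_id": 2}]'), path)
  det <- read_detections(path)
  expect_equal(nrow(det), 2L)
  expect_equal(det$x_min[1], 10); expect_equal(det$x_max[1], 40)
  expect_equal(det$y_min[1], 20); expect_equal(det$y_max[1], 60)
  expect_equal(det$score, c(0.9, 0.4))
  expect_equal(det$frame_index, c(0L, 1L))
})
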
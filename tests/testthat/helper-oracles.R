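## Independent oracles, implemented straight from first principles and kept
## free of the package's own code paths.

## Brute-force Local Outlier Factor, written directly from the Breunig et al.
## definitions with explicit loops: k-distance, tie-inclusive k-neighbourhood,
## reachability distance, local reachability density, LOF. Densities at
## coincident points are capped at 1e10 (same convention as the package and
## the reference library implementation).
brute_lof <- function(points, k) {
  n <- nrow(points)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d[i, j] <- sqrt(sum((points[i, ] - points[j, ])^2))
  }
  kdist <- numeric(n)
  nbhd <- vector("list", n)
  for (i in 1:n) {
    others <- sort(d[i, -i])
    kdist[i] <- others[min(k, n - 1)]
    nbhd[[i]] <- setdiff(which(d[i, ] <= kdist[i] + 1e-12), i)
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    reach <- numeric(0)
    for (o in nbhd[[i]]) reach <- c(reach, max(kdist[o], d[i, o]))
    m <- mean(reach)
    lrd[i] <- if (m <= 0) 1e10 else min(1 / m, 1e10)
  }
  lof <- numeric(n)
  for (i in 1:n) {
    ratios <- numeric(0)
    for (o in nbhd[[i]]) ratios <- c(ratios, lrd[o] / lrd[i])
    lof[i] <- mean(ratios)
  }
  lof
}

## Brute-force rasterization oracle: per-pixel nonzero-winding test via the
## crossing rule, double loop over the frame.
brute_raster_count <- function(polygon, width, height) {
  nv <- nrow(polygon)
  inside <- function(px, py) {
    wn <- 0L
    for (e in 1:nv) {
      x1 <- polygon[e, 1]; y1 <- polygon[e, 2]
      f <- if (e == nv) 1L else e + 1L
      x2 <- polygon[f, 1]; y2 <- polygon[f, 2]
      if (y1 <= py && py < y2) {
        if ((x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) > 0) wn <- wn + 1L
      } else if (y2 <= py && py < y1) {
        if ((x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) < 0) wn <- wn - 1L
      }
    }
    wn != 0L
  }
  cnt <- 0L
  for (i in 1:width) for (j in 1:height) {
    if (inside(i - 0.5, j - 0.5)) cnt <- cnt + 1L
  }
  cnt
}

## rectangle polygon helpers
rect_polygon <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

## rectangle of given length/width centred at `center`, rotated by angle_deg
rotated_rect <- function(center, length, width, angle_deg) {
  a <- angle_deg * pi / 180
  d <- c(cos(a), sin(a)); nv <- c(-sin(a), cos(a))
  h <- length / 2; w <- width / 2
  rbind(center + h * d + w * nv, center + h * d - w * nv,
        center - h * d - w * nv, center - h * d + w * nv)
}

## direction angle mod 180 in degrees
dir_angle_deg <- function(v) (atan2(v[2], v[1]) * 180 / pi) %% 180

angdiff180 <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

## build an annotated frame from a list of polygons
frame_from_polys <- function(polys, spec, true_gaze = NULL, labels = NULL) {
  masks <- lapply(seq_along(polys), function(i) {
    instrument_mask(if (is.null(labels)) paste0("tool", i) else labels[i],
                    polygon = polys[[i]])
  })
  annotated_frame(0L, masks, spec, true_gaze = true_gaze)
}

## minimal Labelme JSON writer used to build reader fixtures in tests,
## independent of write_labelme()
write_labelme_fixture <- function(path, shapes, width = 100, height = 80) {
  shp <- vapply(shapes, function(s) {
    pts <- paste(sprintf("[%g, %g]", s$points[, 1], s$points[, 2]),
                 collapse = ", ")
    sprintf('{"label": "%s", "shape_type": "%s", "points": [%s]}',
            s$label, s$shape_type, pts)
  }, character(1))
  writeLines(sprintf(
    '{"version": "5.0.1", "shapes": [%s], "imageWidth": %d, "imageHeight": %d}',
    paste(shp, collapse = ", "), width, height), path)
}
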
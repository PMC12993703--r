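## convenience: an axis through `p` with direction angle `deg`
axis_through <- function(p, deg) {
  d <- c(cos(deg * pi / 180), sin(deg * pi / 180))
  instrument_axis(center = p, direction = d,
                  end_a = p - 50 * d, end_b = p + 50 * d, elongation = 10)
}

test_that("intersect_pair solves perpendicular and oblique crossings", {
  ## horizontal line through (0,100) x vertical line through (100,0)
  h <- axis_through(c(0, 100), 0)
  v <- axis_through(c(100, 0), 90)
  expect_equal(intersect_pair(h, v), c(100, 100), tolerance = 1e-9)

  ## y = x and y = -x + 10 cross at (5,5)
  a <- axis_through(c(0, 0), 45)
  b <- axis_through(c(0, 10), -45)
  expect_equal(intersect_pair(a, b), c(5, 5), tolerance = 1e-9)
})

test_that("intersect_pair rejects parallel and near-parallel axes", {
  a <- axis_through(c(0, 0), 0)
  b <- axis_through(c(0, 10), 0)
  expect_null(intersect_pair(a, b))
  c_ <- axis_through(c(0, 10), 1)   # 1 degree < default 2-degree guard
  expect_null(intersect_pair(a, c_))
  expect_false(is.null(intersect_pair(a, c_, min_angle = 0.5)))
})

test_that("all_intersections enumerates pairs and applies both guards", {
  spec <- frame_spec(1440, 1080)
  p <- c(700, 500)
  ## 3 mutually non-parallel axes through one point: 3 identical points
  axes3 <- list(axis_through(p, 0), axis_through(p, 60), axis_through(p, 120))
  xs <- all_intersections(axes3, spec)
  expect_equal(nrow(xs$points), 3L)
  expect_true(all(abs(xs$points[, 1] - p[1]) < 1e-6))
  expect_true(all(abs(xs$points[, 2] - p[2]) < 1e-6))
  expect_equal(nrow(xs$pair_ids), 3L)
  expect_true(all(is.na(xs$inlier_flags)))

  ## every point lies on both parent axes' lines
  for (r in seq_len(nrow(xs$points))) {
    for (ai in xs$pair_ids[r, ]) {
      ax <- axes3[[ai]]
      v <- xs$points[r, ] - ax$center
      expect_lt(abs(v[1] * ax$direction[2] - v[2] * ax$direction[1]), 1e-6)
    }
  }

  ## 2 axes -> at most one point
  expect_equal(nrow(all_intersections(axes3[1:2], spec)$points), 1L)

  ## 4 axes with one parallel pair: C(4,2) = 6 pairs minus the parallel one
  axes4 <- list(axis_through(c(100, 100), 0), axis_through(c(100, 300), 0),
                axis_through(c(400, 100), 70), axis_through(c(700, 200), 130))
  expect_equal(nrow(all_intersections(axes4, spec)$points), 5L)

  ## far-field guard: two axes crossing ~20 diagonals away are dropped
  far <- list(axis_through(c(0, 0), 1), axis_through(c(0, 1200), -1))
  expect_equal(nrow(all_intersections(far, spec, min_angle = 0.5)$points), 0L)
})

test_that("centroid is the per-coordinate mean", {
  expect_equal(centroid(rbind(c(0, 0), c(2, 0), c(1, 3))), c(1, 1))
  expect_equal(centroid(rbind(c(7.5, -2))), c(7.5, -2))
  expect_equal(centroid(rbind(c(-2, 4), c(2, -4))), c(0, 0))
  expect_error(centroid(matrix(numeric(0), 0, 2)), "empty")
})

test_that("LOF scores match the brute-force oracle on the 5-point example", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(5000, 5000))
  for (k in 1:4) {
    expect_equal(lof_scores(pts, k), brute_lof(pts, k), tolerance = 1e-9)
  }
  inlier <- exclude_outliers(pts, lof_params(n_neighbors = 3))
  expect_equal(inlier, c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("LOF scores match the brute-force oracle on random point sets", {
  set.seed(4242)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    pts <- matrix(runif(2 * n, 0, 1000), ncol = 2)
    ## occasionally inject duplicates to exercise the tie/zero-distance path
    if (rep %% 7 == 0) pts[2, ] <- pts[1, ]
    k <- sample(seq_len(n - 1L), 1)
    expect_lt(max(abs(lof_scores(pts, k) - brute_lof(pts, k))), 1e-9)
  }
})

test_that("tiny and degenerate point sets are kept whole", {
  ## below min_points_for_lof: all inliers, wherever they are
  pts3 <- rbind(c(0, 0), c(9999, 0), c(0, 9999))
  expect_equal(exclude_outliers(pts3), rep(TRUE, 3))
  ## identical points: zero distances, no density contrast
  same <- matrix(rep(c(3, 4), each = 5), ncol = 2)
  expect_equal(exclude_outliers(same), rep(TRUE, 5))
  expect_error(exclude_outliers(matrix(numeric(0), 0, 2)), "empty")
})

test_that("at least one inlier always remains", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(4:10, 1)
    pts <- matrix(rnorm(2 * n, sd = 500), ncol = 2)
    expect_true(any(exclude_outliers(pts)))
    expect_true(any(exclude_outliers(pts, lof_params(contamination = 0.5))))
  }
})

test_that("numeric contamination flags the floor(c*n) largest scores", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(50, 50), c(60, 60))
  inl <- exclude_outliers(pts, lof_params(n_neighbors = 2, contamination = 1 / 3))
  expect_equal(sum(!inl), 2L)
  expect_equal(which(!inl), c(5L, 6L))
})

test_that("estimate_gaze recovers a concurrent-axes frame", {
  spec <- frame_spec(1440, 1080)
  g <- c(700, 500)
  polys <- lapply(c(15, 80, 140), function(ang) {
    d <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    rotated_rect(g + 260 * d, 300, 28, ang)
  })
  est <- estimate_gaze(frame_from_polys(polys, spec))
  expect_equal(est$status, "ok")
  expect_equal(est$n_axes, 3L)
  expect_equal(est$n_intersections, 3L)
  expect_lt(sqrt(sum((est$point - g)^2)), 2)
  expect_lte(est$n_inliers, est$n_intersections)
})

test_that("estimate_gaze reports the documented failure statuses", {
  spec <- frame_spec(1440, 1080)
  one <- frame_from_polys(list(rotated_rect(c(700, 500), 300, 30, 40)), spec)
  e1 <- estimate_gaze(one)
  expect_equal(e1$status, "insufficient_instruments")
  expect_null(e1$point)

  par2 <- frame_from_polys(list(rotated_rect(c(400, 300), 300, 30, 25),
                                rotated_rect(c(700, 700), 300, 30, 25)), spec)
  e2 <- estimate_gaze(par2)
  expect_equal(e2$status, "no_stable_intersection")
  expect_null(e2$point)
  expect_equal(e2$n_axes, 2L)
})

test_that("estimate_gaze is invariant to instrument order", {
  spec <- frame_spec(1440, 1080)
  g <- c(650, 480)
  polys <- lapply(c(10, 55, 100, 160), function(ang) {
    d <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    rotated_rect(g + 250 * d + c(5, -3), 280, 25, ang)
  })
  e_fwd <- estimate_gaze(frame_from_polys(polys, spec))
  e_rev <- estimate_gaze(frame_from_polys(rev(polys), spec))
  expect_equal(e_fwd$status, "ok")
  expect_equal(e_fwd$point, e_rev$point, tolerance = 1e-9)
  expect_equal(e_fwd$n_inliers, e_rev$n_inliers)
})

test_that("the estimate lies in the convex hull of the inlier intersections", {
  spec <- frame_spec(1440, 1080)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    pts <- matrix(runif(2 * n, 100, 1000), ncol = 2)
    inl <- exclude_outliers(pts)
    kept <- pts[inl, , drop = FALSE]
    g <- centroid(kept)
    if (nrow(kept) >= 3L) {
      hull <- kept[grDevices::chull(kept), , drop = FALSE]
      ## g inside hull iff adding it leaves the hull vertex set unchanged
      hull2 <- rbind(hull, g)
      expect_false((nrow(hull) + 1L) %in% grDevices::chull(hull2))
    } else {
      expect_gte(g[1], min(kept[, 1]) - 1e-9)
      expect_lte(g[1], max(kept[, 1]) + 1e-9)
    }
  }
})

test_that("gaze_config rejects unknown keys", {
  expect_error(gaze_config(axis = list(min_elong = 3)), "unknown key")
  expect_error(gaze_config(intersect = list(angle = 1)), "unknown key")
  cfg <- gaze_config(axis = list(min_elongation = 3))
  expect_equal(cfg$axis$min_elongation, 3)
  expect_equal(cfg$axis$min_area, 200)  # untouched defaults survive
})
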
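## Polygon rasterization by scanline.
##
## A pixel is set iff its centre (col - 0.5, row - 0.5) lies inside the
## polygon. Masks are simple polygons (a cleaned annotation outline), for
## which the even-odd and nonzero winding rules coincide; the scanline fill
## below is therefore equivalent to the nonzero rule on valid input.
## Horizontal spans are half-open [x_enter, x_exit) so shared edges between
## adjacent polygons are not double-counted.

#' Shoelace area of a polygon
#'
#' @param polygon `n x 2` vertex matrix.
#' @return Absolute enclosed area in px^2.
#' @export
polygon_area <- function(polygon) {
  p <- as_point_matrix(polygon)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

## Set-pixel centres of a polygon clipped to the frame.
## Returns list(x, y, i, j): continuous centre coords and 1-based col/row.
polygon_pixels <- function(polygon, spec) {
  p <- as_point_matrix(polygon)
  n <- nrow(p)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])

  j_lo <- max(1L, as.integer(ceiling(min(y1) + 0.5)))
  j_hi <- min(spec$height, as.integer(floor(max(y1) + 0.5)))
  if (j_lo > j_hi) {
    return(list(x = numeric(0), y = numeric(0), i = integer(0), j = integer(0)))
  }
  rows <- j_lo:j_hi
  yc <- rows - 0.5  # scanline y per row

  ## crossings[r, e]: x where edge e crosses scanline r (NA if it doesn't).
  ## Half-open vertex rule (y_min <= y < y_max) handles vertices exactly once.
  Y1 <- matrix(y1, length(yc), n, byrow = TRUE)
  Y2 <- matrix(y2, length(yc), n, byrow = TRUE)
  X1 <- matrix(x1, length(yc), n, byrow = TRUE)
  X2 <- matrix(x2, length(yc), n, byrow = TRUE)
  YC <- matrix(yc, length(yc), n)
  crosses <- (Y1 <= YC & YC < Y2) | (Y2 <= YC & YC < Y1)
  XS <- X1 + (YC - Y1) * (X2 - X1) / (Y2 - Y1)
  XS[!crosses] <- NA_real_

  ncross <- rowSums(crosses)
  out_i <- integer(0); out_j <- integer(0)

  if (all(ncross <= 2L)) {
    ## convex / simple-span fast path: at most one span per row, vectorised
    keep <- ncross == 2L
    if (any(keep)) {
      a <- apply(XS[keep, , drop = FALSE], 1L, min, na.rm = TRUE)
      b <- apply(XS[keep, , drop = FALSE], 1L, max, na.rm = TRUE)
      i_min <- pmax(1L, as.integer(ceiling(a + 0.5)))
      i_max <- pmin(spec$width, as.integer(floor(b + 0.5 - 1e-9)))
      cnt <- pmax(0L, i_max - i_min + 1L)
      nz <- cnt > 0L
      if (any(nz)) {
        out_i <- as.integer(sequence(cnt[nz], from = i_min[nz]))
        out_j <- rep.int(rows[keep][nz], cnt[nz])
      }
    }
  } else {
    ## general even-odd fill, row by row
    acc_i <- vector("list", length(rows))
    for (r in seq_along(rows)) {
      xs <- sort(XS[r, !is.na(XS[r, ])])
      if (length(xs) < 2L) next
      cols <- integer(0)
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        i_min <- max(1L, as.integer(ceiling(xs[k] + 0.5)))
        i_max <- min(spec$width, as.integer(floor(xs[k + 1L] + 0.5 - 1e-9)))
        if (i_min <= i_max) cols <- c(cols, i_min:i_max)
      }
      acc_i[[r]] <- cols
    }
    cnt <- lengths(acc_i)
    out_i <- unlist(acc_i, use.names = FALSE)
    if (is.null(out_i)) out_i <- integer(0)
    out_j <- rep.int(rows, cnt)
  }
  list(x = out_i - 0.5, y = out_j - 0.5, i = out_i, j = out_j)
}

#' Rasterize an instrument polygon
#'
#' Converts a polygon-carried [instrument_mask()] to the raster
#' representation: a logical `height x width` matrix where a pixel is set iff
#' its centre lies inside the polygon (scanline fill; for the simple polygons
#' the data model requires, even-odd and nonzero winding agree). The polygon
#' is retained alongside the raster.
#'
#' @param mask an [instrument_mask()] carrying a polygon.
#' @param spec the [frame_spec()] giving raster dimensions.
#' @return An `instrument_mask` with both `raster` and `polygon` set.
#' @export
polygon_to_raster <- function(mask, spec) {
  stopifnot(inherits(mask, "instrument_mask"), inherits(spec, "frame_spec"))
  if (is.null(mask$polygon)) stop("mask does not carry a polygon")
  px <- polygon_pixels(mask$polygon, spec)
  if (length(px$i) == 0L) {
    stop("degenerate mask: polygon covers no pixel centres inside the frame")
  }
  raster <- matrix(FALSE, nrow = spec$height, ncol = spec$width)
  raster[cbind(px$j, px$i)] <- TRUE
  out <- mask
  out$raster <- raster
  out
}

## set-pixel centres of a mask in either representation
mask_pixels <- function(mask, spec) {
  if (!is.null(mask$raster)) {
    idx <- which(mask$raster, arr.ind = TRUE)
    return(list(x = idx[, 2] - 0.5, y = idx[, 1] - 0.5))
  }
  px <- polygon_pixels(mask$polygon, spec)
  list(x = px$x, y = px$y)
}
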
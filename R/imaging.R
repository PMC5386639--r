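# Low-level raster helpers: shifts, Laplacian, local maxima, integral images
# and area-weighted resampling.  Images are matrices indexed [row, col] =
# [y + 1, x + 1] in the package's 0-based (x, y) convention.

## shift a matrix by (dy, dx) with edge replication
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

## 4-neighbor discrete Laplacian with replicated edges
laplacian <- function(m) {
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
    shift_mat(m, 0, 1) + shift_mat(m, 0, -1) - 4 * m
}

## logical matrix: pixel >= all 8 neighbors
local_maxima <- function(m) {
  ok <- matrix(TRUE, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & (m >= shift_mat(m, dy, dx))
  }
  ok
}

## triangle ("knee") threshold on a positive-valued response distribution:
## the histogram bin furthest below the line from the histogram peak to its
## upper tail.  Robust when most pixels are background and a small bright
## population forms a tail.
knee_threshold <- function(v, bins = 512L) {
  v <- v[is.finite(v) & v > 0]
  if (length(v) < 10L) return(Inf)
  h <- graphics::hist(v, breaks = bins, plot = FALSE)
  cnt <- h$counts; mid <- h$mids
  b0 <- which.max(cnt)
  b1 <- max(which(cnt > 0))
  if (b1 <= b0) return(max(v))
  # distance from (i, cnt[i]) to the peak-to-tail chord
  x0 <- b0; y0 <- cnt[b0]; x1 <- b1; y1 <- cnt[b1]
  i <- b0:b1
  d <- abs((y1 - y0) * i - (x1 - x0) * cnt[i] + x1 * y0 - y1 * x0)
  mid[i[which.max(d)]]
}

## integral image: (nr+1) x (nc+1), SI[a+1, b+1] = sum(img[1:a, 1:b])
integral_image <- function(img) {
  si <- apply(img, 2, cumsum)
  si <- t(apply(si, 1, cumsum))
  rbind(0, cbind(0, si))
}

## evaluate an integral image at fractional (row, col) grids by separable
## linear interpolation -- exact for piecewise-constant pixel densities
interp_integral <- function(si, yb, xb) {
  fy <- pmin(pmax(yb, 0), nrow(si) - 1)
  fx <- pmin(pmax(xb, 0), ncol(si) - 1)
  y0 <- floor(fy); wy <- fy - y0
  x0 <- floor(fx); wx <- fx - x0
  rows <- si[y0 + 1L, , drop = FALSE] * (1 - wy) +
    si[pmin(y0 + 2L, nrow(si)), , drop = FALSE] * wy
  rows[, x0 + 1L, drop = FALSE] * rep(1 - wx, each = nrow(rows)) +
    rows[, pmin(x0 + 2L, ncol(si)), drop = FALSE] * rep(wx, each = nrow(rows))
}

#' Area-weighted image resampling
#'
#' Each target pixel takes the exact area-weighted mean of the source pixels
#' it covers (box filter), computed from an interpolated integral image.
#' The natural use is downscaling (factor < 1), e.g. matching a
#' high-magnification field to the pixel size of a lower-magnification scan.
#'
#' @param img Numeric matrix.
#' @param factor Linear scale factor (> 0); output size `round(dim * factor)`.
#' @return Resampled matrix.
#' @export
resize_area <- function(img, factor) {
  stopifnot(is.matrix(img), factor > 0)
  if (factor == 1) return(img)
  oh <- max(1L, round(nrow(img) * factor))
  ow <- max(1L, round(ncol(img) * factor))
  yb <- seq(0, nrow(img), length.out = oh + 1L)
  xb <- seq(0, ncol(img), length.out = ow + 1L)
  g <- interp_integral(integral_image(img), yb, xb)
  s <- g[-1, -1, drop = FALSE] - g[-1, -(ow + 1L), drop = FALSE] -
    g[-(oh + 1L), -1, drop = FALSE] + g[-(oh + 1L), -(ow + 1L), drop = FALSE]
  area <- outer(diff(yb), diff(xb))
  s / area
}
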
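# Polygon primitives shared by the scoring and simulation code.
#
# Conventions: polygons are n x 2 numeric matrices of (x, y) vertices in pixel
# units, 0-based coordinates, x = column (rightward), y = row (downward),
# implicitly closed (last vertex joins the first).

#' Signed and absolute polygon area (shoelace)
#'
#' @param poly n x 2 matrix of (x, y) vertices.
#' @return Absolute area in squared input units.
#' @keywords internal
polygon_area <- function(poly) {
  abs(pracma::polyarea(poly[, 1], poly[, 2]))
}

#' Polygon centroid
#' @param poly n x 2 vertex matrix.
#' @return Length-2 numeric (x, y).
#' @keywords internal
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x, x[1]); ys <- c(y, y[1])
  cross <- xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)]
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  cx <- sum((xs[-length(xs)] + xs[-1]) * cross) / (6 * a)
  cy <- sum((ys[-length(ys)] + ys[-1]) * cross) / (6 * a)
  c(cx, cy)
}

#' Test whether points fall inside (or on the border of) a polygon
#'
#' @param x,y Point coordinates (vectors of equal length).
#' @param poly n x 2 vertex matrix.
#' @return Logical vector.
#' @keywords internal
points_in_polygon <- function(x, y, poly) {
  if (length(x) == 0L) return(logical(0))
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

#' Minimum distance from points to a polygon boundary
#'
#' Distance to the closed polyline, not the filled region: points inside the
#' polygon get their (positive) distance to the nearest edge.
#'
#' @param x,y Point coordinates.
#' @param poly n x 2 vertex matrix.
#' @return Numeric vector of distances.
#' @keywords internal
dist_to_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  ex <- qx - px; ey <- qy - py
  len2 <- ex^2 + ey^2
  d2 <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    if (len2[i] < .Machine$double.eps) {
      di <- (x - px[i])^2 + (y - py[i])^2
    } else {
      t <- ((x - px[i]) * ex[i] + (y - py[i]) * ey[i]) / len2[i]
      t <- pmin(1, pmax(0, t))
      di <- (x - (px[i] + t * ex[i]))^2 + (y - (py[i] + t * ey[i]))^2
    }
    d2 <- pmin(d2, di)
  }
  sqrt(d2)
}

#' Check that a polygon is simple (no self-intersection)
#'
#' O(n^2) segment-pair test; adequate for nucleus outlines (tens of vertices).
#' @param poly n x 2 vertex matrix.
#' @return TRUE/FALSE.
#' @keywords internal
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  seg <- cbind(poly, rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]))
  intersects <- function(a, b) {
    # proper intersection of open segments a and b
    d1 <- sign((b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1]))
    d2 <- sign((b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1]))
    d3 <- sign((a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1]))
    d4 <- sign((a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1]))
    d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    j <- i + 2L
    while (j <= jmax) {
      if (intersects(seg[i, ], seg[j, ])) return(FALSE)
      j <- j + 1L
    }
  }
  TRUE
}

#' Round-join outward offset (dilation) of a polygon
#'
#' Offsets every edge outward by \code{margin} and joins consecutive edges with
#' circular arcs at convex corners, i.e. the boundary of the Minkowski sum of
#' the polygon with a disc of radius \code{margin}.  Exact (up to arc
#' discretization) for convex polygons; for mildly concave outlines it is
#' accurate while \code{margin} is small relative to the local feature size,
#' which holds for nucleus outlines.
#'
#' @param poly n x 2 vertex matrix.
#' @param margin Offset distance (>= 0) in the same units as the vertices.
#' @param arc_step Maximum angular step (radians) used to discretize corner
#'   arcs.
#' @return Vertex matrix of the dilated polygon.
#' @keywords internal
offset_polygon <- function(poly, margin, arc_step = pi / 90) {
  if (margin == 0) return(poly)
  stopifnot(margin > 0)
  # normalise to positive (counter-clockwise) shoelace orientation so that the
  # outward normal of an edge with direction (ex, ey) is (ey, -ex)
  if (pracma::polyarea(poly[, 1], poly[, 2]) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  n <- nrow(poly)
  out_x <- numeric(0); out_y <- numeric(0)
  for (i in seq_len(n)) {
    p0 <- poly[if (i == 1L) n else i - 1L, ]
    p1 <- poly[i, ]
    p2 <- poly[if (i == n) 1L else i + 1L, ]
    e_in <- p1 - p0; e_out <- p2 - p1
    n_in <- c(e_in[2], -e_in[1]) / sqrt(sum(e_in^2))
    n_out <- c(e_out[2], -e_out[1]) / sqrt(sum(e_out^2))
    cross_z <- e_in[1] * e_out[2] - e_in[2] * e_out[1]
    if (cross_z > 0) {
      # convex corner: arc from n_in to n_out around p1
      a0 <- atan2(n_in[2], n_in[1])
      a1 <- atan2(n_out[2], n_out[1])
      da <- a1 - a0
      while (da < 0) da <- da + 2 * pi
      k <- max(1L, ceiling(abs(da) / arc_step))
      ang <- a0 + da * (0:k) / k
      out_x <- c(out_x, p1[1] + margin * cos(ang))
      out_y <- c(out_y, p1[2] + margin * sin(ang))
    } else {
      # reflex corner: intersect the two offset edges (miter)
      a1s <- p1 + margin * n_in
      a2s <- p1 + margin * n_out
      d1 <- e_in; d2 <- e_out
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      if (abs(den) < 1e-12) {
        out_x <- c(out_x, a1s[1]); out_y <- c(out_y, a1s[2])
      } else {
        t <- ((a2s[1] - a1s[1]) * d2[2] - (a2s[2] - a1s[2]) * d2[1]) / den
        out_x <- c(out_x, a1s[1] + t * d1[1])
        out_y <- c(out_y, a1s[2] + t * d1[2])
      }
    }
  }
  cbind(x = out_x, y = out_y)
}

#' Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' @param poly n x 2 vertex matrix.
#' @param xlim,ylim Length-2 numeric bounds.
#' @return Clipped vertex matrix (possibly 0 rows).
#' @keywords internal
clip_polygon_rect <- function(poly, xlim, ylim) {
  if (all(poly[, 1] >= xlim[1] & poly[, 1] <= xlim[2] &
            poly[, 2] >= ylim[1] & poly[, 2] <= ylim[2])) {
    return(poly)
  }
  clip_half <- function(pts, inside, intersect) {
    if (nrow(pts) == 0L) return(pts)
    n <- nrow(pts)
    res <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prv <- pts[if (i == 1L) n else i - 1L, ]
      cin <- inside(cur); pin <- inside(prv)
      if (cin) {
        if (!pin) res <- rbind(res, intersect(prv, cur))
        res <- rbind(res, cur)
      } else if (pin) {
        res <- rbind(res, intersect(prv, cur))
      }
    }
    res
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  pts <- poly
  pts <- clip_half(pts, function(p) p[1] >= xlim[1], function(p, q) ix(p, q, xlim[1], 1))
  pts <- clip_half(pts, function(p) p[1] <= xlim[2], function(p, q) ix(p, q, xlim[2], 1))
  pts <- clip_half(pts, function(p) p[2] >= ylim[1], function(p, q) ix(p, q, ylim[1], 2))
  pts <- clip_half(pts, function(p) p[2] <= ylim[2], function(p, q) ix(p, q, ylim[2], 2))
  colnames(pts) <- c("x", "y")
  pts
}
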
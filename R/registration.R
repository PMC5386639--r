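# Mapping spot coordinates from high-magnification fields onto stitched
# low-magnification scans (and onward onto an H&E scan) via a two-stage
# affine chain: A1 from normalized cross-correlation template matching
# (scaling + translation), A2 from manually picked reference-point pairs
# (full least-squares affine).  Composite mapping of the dots D is
# D' = A2 A1 D in homogeneous coordinates.

#' Affine transform constructors
#'
#' 3 x 3 homogeneous matrices acting on 2-D (x, y) points: `affine_scale`
#' scales about the origin, `affine_translate` shifts, `affine_identity` is
#' the identity.  Compose with `%*%` (the right-hand transform applies
#' first).
#'
#' @param s Scale factor.
#' @param tx,ty Translation components.
#' @return 3 x 3 numeric matrix.
#' @export
affine_identity <- function() diag(3)

#' @rdname affine_identity
#' @export
affine_scale <- function(s) diag(c(s, s, 1))

#' @rdname affine_identity
#' @export
affine_translate <- function(tx, ty) {
  a <- diag(3)
  a[1, 3] <- tx; a[2, 3] <- ty
  a
}

#' Apply an affine transform to 2-D points
#'
#' @param a 3 x 3 homogeneous matrix.
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) points.
#' @return n x 2 matrix of transformed points.
#' @export
apply_affine <- function(a, xy) {
  stopifnot(all(dim(a) == c(3, 3)))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  h <- a %*% rbind(t(xy), 1)
  out <- t(h[1:2, , drop = FALSE] / rep(h[3, ], each = 2))
  colnames(out) <- c("x", "y")
  out
}

#' Normalized cross-correlation over all valid template placements
#'
#' Fast NCC: the numerator is the FFT cross-correlation of the scan with
#' the zero-mean template; per-window scan means and variances come from
#' integral images.  Windows with (near) zero variance get correlation 0.
#'
#' @param template,scan Numeric matrices; the template must fit inside the
#'   scan.
#' @return Matrix of correlations, entry (i, j) for the placement with the
#'   template's top-left pixel at scan row i, column j (1-based).
#' @export
ncc_matrix <- function(template, scan) {
  th <- nrow(template); tw <- ncol(template)
  sh <- nrow(scan); sw <- ncol(scan)
  if (th > sh || tw > sw) stop("template larger than scan")
  t0 <- template - mean(template)
  t_ss <- sum(t0^2)
  tpad <- matrix(0, sh, sw)
  tpad[1:th, 1:tw] <- t0
  cc <- Re(stats::fft(stats::fft(scan) * Conj(stats::fft(tpad)), inverse = TRUE)) /
    (sh * sw)
  si <- integral_image(scan)
  si2 <- integral_image(scan^2)
  box <- function(s) {
    s[(th + 1):(sh + 1), (tw + 1):(sw + 1), drop = FALSE] -
      s[(th + 1):(sh + 1), 1:(sw - tw + 1), drop = FALSE] -
      s[1:(sh - th + 1), (tw + 1):(sw + 1), drop = FALSE] +
      s[1:(sh - th + 1), 1:(sw - tw + 1), drop = FALSE]
  }
  n <- th * tw
  wsum <- box(si)
  wvar <- box(si2) - wsum^2 / n
  den <- sqrt(pmax(wvar, 0) * t_ss)
  num <- cc[1:(sh - th + 1), 1:(sw - tw + 1), drop = FALSE]
  out <- num / den
  out[!is.finite(out) | den < 1e-8 * sqrt(t_ss / n) * n] <- 0
  out
}

#' Register a high-magnification field onto a scan (transform A1)
#'
#' The field image is rescaled to the scan's pixel size by area-weighted
#' resampling, matched against the scan by normalized cross-correlation
#' over all valid placements, and the correlation peak taken as the
#' placement.  A1 is the scaling followed by the peak translation:
#' `x_scan = scale_ratio * x_fov + (scale_ratio - 1)/2 + tx` (the half-pixel
#' term maps pixel centers to pixel centers).  No rotation is fitted;
#' residual correction belongs to A2.
#'
#' @param fov_img Field image (matrix).
#' @param scan_img Scan image (matrix).
#' @param scale_ratio Field pixel size / scan pixel size (< 1 downsizes the
#'   field image).
#' @param min_confidence Peak correlations below this floor set
#'   `flagged = TRUE`.
#' @return List: `A1` (3 x 3), `translation` c(tx, ty), `confidence` (peak
#'   NCC), `flagged`.
#' @export
register_highmag <- function(fov_img, scan_img, scale_ratio = 1,
                             min_confidence = 0.5) {
  stopifnot(is.matrix(fov_img), is.matrix(scan_img), scale_ratio > 0)
  tmpl <- if (scale_ratio == 1) fov_img else resize_area(fov_img, scale_ratio)
  cc <- ncc_matrix(tmpl, scan_img)
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ty <- peak[1] - 1; tx <- peak[2] - 1
  a1 <- affine_translate(tx, ty) %*%
    affine_translate((scale_ratio - 1) / 2, (scale_ratio - 1) / 2) %*%
    affine_scale(scale_ratio)
  list(A1 = a1, translation = c(tx = unname(tx), ty = unname(ty)),
       confidence = max(cc), flagged = max(cc) < min_confidence)
}

#' Least-squares affine transform from reference-point pairs (A2)
#'
#' Fits the 6-parameter affine minimizing the summed squared residuals
#' `||A2 p - q||^2` over the point pairs.  Needs at least 3 non-collinear
#' pairs.
#'
#' @param src,dst n x 2 matrices of corresponding (x, y) points.
#' @return List: `A2` (3 x 3), `rms` (residual root-mean-square distance).
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) == nrow(dst), ncol(src) == 2, ncol(dst) == 2)
  if (nrow(src) < 3L) stop("need >= 3 point pairs")
  x <- cbind(src, 1)
  if (qr(x)$rank < 3L) stop("reference points are collinear")
  coef <- qr.solve(x, dst)          # 3 x 2: columns map to x' and y'
  a <- rbind(t(coef), c(0, 0, 1))
  dimnames(a) <- NULL
  fit <- x %*% coef
  rms <- sqrt(mean(rowSums((fit - dst)^2)))
  list(A2 = a, rms = rms)
}

#' Map spot coordinates through the two-stage transform chain
#'
#' Each spot's homogeneous coordinate is multiplied by `A2 %*% A1` (A1
#' applies first).
#'
#' @param spots A [spot_table()] (or data frame with `x_px`, `y_px`).
#' @param A1,A2 3 x 3 transforms; either may be omitted (identity).
#' @return `spots` with `x_px`, `y_px` replaced by scan coordinates.
#' @export
map_spots <- function(spots, A1 = affine_identity(), A2 = affine_identity()) {
  xy <- apply_affine(A2 %*% A1, cbind(spots$x_px, spots$y_px))
  spots$x_px <- xy[, 1]
  spots$y_px <- xy[, 2]
  spots
}
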
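# Structure-tensor detection of nuclei-containing regions and densities
# within them.  The determinant of the gradient structure tensor is high
# where the image shows oriented local structure in two directions (chromatin
# texture, nuclear boundaries) and near zero in flat stroma.

#' Detect nuclei-containing regions with the gradient structure tensor
#'
#' Computes per pixel the 2 x 2 structure tensor from Gaussian-derivative
#' gradients at `sigma_gradient_nm`, smooths its components with a Gaussian
#' of `sigma_tensor_nm`, and thresholds the tensor determinant.  Defaults
#' are 250 nm / 875 nm, i.e. 2 px and 7 px at 125 nm/px.  With
#' `det_threshold = NULL` a threshold is chosen automatically by Otsu's
#' method on the fourth root of the determinant (the determinant scales with
#' the fourth power of image intensity, so the root stabilizes the
#' histogram); in the workflow the threshold is meant to be chosen once and
#' reused across all images of a study.
#'
#' @param img Numeric matrix: the z-projection of the DAPI stack.
#' @param meta [fov_meta()] supplying `pixel_size_nm` (or a single number,
#'   the pixel size in nm).
#' @param sigma_gradient_nm,sigma_tensor_nm Tensor scales in nanometers.
#' @param det_threshold Threshold on the determinant; `NULL` = automatic.
#' @return Object of class `region_mask`: list with `mask` (logical matrix),
#'   `det` (determinant image), `det_threshold`, and the scales in px.
#' @export
nuclei_mask <- function(img, meta, sigma_gradient_nm = 250,
                        sigma_tensor_nm = 875, det_threshold = NULL) {
  if (!is.matrix(img) || !is.numeric(img)) stop("img must be a 2-D numeric matrix")
  pixel_size_nm <- if (inherits(meta, "fov_meta")) meta$pixel_size_nm else meta
  sg <- sigma_gradient_nm / pixel_size_nm
  st <- sigma_tensor_nm / pixel_size_nm
  sm <- as.matrix(EBImage::gblur(img, sigma = sg))
  gx <- (shift_mat(sm, 0, -1) - shift_mat(sm, 0, 1)) / 2
  gy <- (shift_mat(sm, -1, 0) - shift_mat(sm, 1, 0)) / 2
  jxx <- as.matrix(EBImage::gblur(gx * gx, sigma = st))
  jyy <- as.matrix(EBImage::gblur(gy * gy, sigma = st))
  jxy <- as.matrix(EBImage::gblur(gx * gy, sigma = st))
  det <- jxx * jyy - jxy^2
  if (is.null(det_threshold)) {
    pos <- pmax(det, 0)
    r <- range(pos^(1 / 4))
    det_threshold <- if (diff(r) < .Machine$double.eps) Inf else
      (EBImage::otsu(pos^(1 / 4), range = r))^4
  }
  structure(list(mask = det > det_threshold, det = det,
                 det_threshold = det_threshold,
                 sigma_gradient_px = sg, sigma_tensor_px = st),
            class = "region_mask")
}

#' Transcript density within a region mask
#'
#' Counts the spots whose (x, y) position falls on a masked pixel and
#' divides by the mask volume (mask area in um^2 times the imaging depth).
#'
#' @param spots A [spot_table()] of the field (one channel, or filter first).
#' @param mask A [nuclei_mask()] result or a logical matrix.
#' @param meta The field's [fov_meta()].
#' @return List: `density` (dots/um^3, `NA` and `flagged = TRUE` for an
#'   empty mask), `n_spots`, `mask_area_um2`, `flagged`.
#' @export
mask_density <- function(spots, mask, meta) {
  stopifnot(inherits(meta, "fov_meta"))
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  stopifnot(is.matrix(m), is.logical(m))
  if (!all(dim(m) == c(meta$height_px, meta$width_px))) {
    stop("mask shape does not match the field")
  }
  area_um2 <- sum(m) * meta$pixel_size_um^2
  if (area_um2 == 0) {
    return(list(density = NA_real_, n_spots = 0L, mask_area_um2 = 0, flagged = TRUE))
  }
  ri <- pmin(pmax(round(spots$y_px) + 1L, 1L), nrow(m))
  ci <- pmin(pmax(round(spots$x_px) + 1L, 1L), ncol(m))
  inside <- m[cbind(ri, ci)]
  n <- sum(inside)
  list(density = n / (area_um2 * meta$depth_um), n_spots = as.integer(n),
       mask_area_um2 = area_um2, flagged = FALSE)
}
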
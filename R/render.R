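# Rendering of synthetic fields: smFISH spots as 2-D Gaussians on their
# focal plane, and a DAPI-like nuclear channel from the filled nucleus
# polygons with chromatin-like texture.

## add one isotropic 2-D Gaussian of amplitude a at 0-based (x0, y0)
add_gaussian <- function(img, x0, y0, a, sigma) {
  r <- ceiling(5 * sigma) + 1L
  cx <- round(x0) + 1L; cy <- round(y0) + 1L
  xs <- max(1L, cx - r):min(ncol(img), cx + r)
  ys <- max(1L, cy - r):min(nrow(img), cy + r)
  if (!length(xs) || !length(ys)) return(img)
  gx <- exp(-((xs - 1 - x0)^2) / (2 * sigma^2))
  gy <- exp(-((ys - 1 - y0)^2) / (2 * sigma^2))
  img[ys, xs] <- img[ys, xs] + a * outer(gy, gx)
  img
}

## fill a polygon footprint (logical matrix) on the pixel-center lattice
rasterize_polygon <- function(poly, height, width) {
  xs <- max(1L, floor(min(poly[, 1])) + 1L):min(width, ceiling(max(poly[, 1])) + 1L)
  ys <- max(1L, floor(min(poly[, 2])) + 1L):min(height, ceiling(max(poly[, 2])) + 1L)
  px <- rep(xs - 1L, each = length(ys))
  py <- rep(ys - 1L, times = length(xs))
  inside <- points_in_polygon(px, py, poly)
  m <- matrix(FALSE, height, width)
  m[cbind(py + 1L, px + 1L)[inside, , drop = FALSE]] <- TRUE
  m
}

#' Render a synthetic field of view as image stacks
#'
#' Each smFISH spot becomes an isotropic 2-D Gaussian of standard deviation
#' `psf_sigma_px` and amplitude `spot_amplitude` on its own focal plane (its
#' integrated signal above background is `amplitude * 2 * pi * sigma^2`).
#' The DAPI channel fills the nucleus polygons, adds a smooth chromatin-like
#' texture inside them, and is returned as a single 2-D image (a z-
#' projection stand-in).  Optional noise is Poisson shot noise plus additive
#' Gaussian read noise.
#'
#' @param fov A `sim_fov` bundle from [simulate_fov()], or any list with
#'   `meta`, `spots` and `outlines`.
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param spot_amplitude Peak amplitude of one spot above background.
#' @param background Constant background level.
#' @param noise `"none"` or `"poisson-gaussian"`.
#' @param read_noise_sd Standard deviation of the additive read noise.
#' @param dapi_amplitude Nuclear fill level above background.
#' @param channels Channels to render; default those present in the spots
#'   (pass explicitly to render empty stacks).
#' @param seed Optional integer seed (noise and texture are random).
#' @return List: `channels` (named list of `height x width x n_planes`
#'   arrays, one per channel present in the spots) and `dapi` (matrix).
#' @export
render_image <- function(fov, psf_sigma_px = 1.3, spot_amplitude = 200,
                         background = 100, noise = c("poisson-gaussian", "none"),
                         read_noise_sd = 2, dapi_amplitude = 150,
                         channels = NULL, seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  meta <- fov$meta
  h <- meta$height_px; w <- meta$width_px; np <- meta$n_planes
  if (is.null(channels)) channels <- unique(fov$spots$channel)
  stacks <- lapply(channels, function(ch) {
    s <- fov$spots[fov$spots$channel == ch, , drop = FALSE]
    arr <- array(background, c(h, w, np))
    for (p in 0:(np - 1L)) {
      sp <- s[s$plane == p, , drop = FALSE]
      if (!nrow(sp)) next
      plane <- arr[, , p + 1L]
      for (i in seq_len(nrow(sp))) {
        plane <- add_gaussian(plane, sp$x_px[i], sp$y_px[i],
                              spot_amplitude, psf_sigma_px)
      }
      arr[, , p + 1L] <- plane
    }
    arr
  })
  names(stacks) <- channels
  dapi <- matrix(background, h, w)
  if (length(fov$outlines)) {
    fill <- matrix(FALSE, h, w)
    for (o in fov$outlines) fill <- fill | rasterize_polygon(o$vertices, h, w)
    dapi[fill] <- dapi[fill] + dapi_amplitude
    if (noise == "poisson-gaussian") {
      # chromatin-like multiplicative texture inside nuclei
      tex <- as.matrix(EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = 1.5))
      tex <- tex / stats::sd(tex)
      dapi[fill] <- dapi[fill] * (1 + 0.25 * tex[fill])
    }
  }
  if (noise == "poisson-gaussian") {
    stacks <- lapply(stacks, function(arr) {
      array(stats::rpois(length(arr), lambda = pmax(arr, 0)) +
              stats::rnorm(length(arr), 0, read_noise_sd), dim(arr))
    })
    dapi <- matrix(stats::rpois(length(dapi), pmax(dapi, 0)) +
                     stats::rnorm(length(dapi), 0, read_noise_sd), h, w)
  }
  list(channels = stacks, dapi = dapi)
}

#' Write / read a grayscale image stack as multi-page TIFF
#'
#' Thin wrappers over the `tiff` package; intensities are stored as 32-bit
#' floats scaled by `scale` (use `scale = 1` and pre-scaled data for full
#' fidelity).
#'
#' @param stack `height x width x planes` array (or matrix).
#' @param path File path.
#' @param scale Divisor applied before writing (TIFF floats are unscaled).
#' @return [read_image_stack()] returns an array.
#' @export
write_image_stack <- function(stack, path, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required")
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3]), function(p) stack[, , p] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (p in seq_along(pages)) {
    pg <- pages[[p]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    arr[, , p] <- pg * scale
  }
  arr
}
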
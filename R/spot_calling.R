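# Laplacian-of-Gaussian detection of diffraction-limited spots in
# multi-plane image stacks, and evaluation against ground truth.

#' Spot-calling parameters
#'
#' @param log_sigma_px Scale of the band-pass (Gaussian) filter in pixels;
#'   the default 1.3 px approximates a diffraction-limited PSF sampled at
#'   125 nm/px.
#' @param detection_threshold Cutoff on the (scale-normalized, sign-flipped)
#'   LoG response; `NULL` picks a threshold automatically at the knee of the
#'   response histogram, pooled over the stack.
#' @param min_separation_px Non-maximum-suppression radius.
#' @param z_merge Collapse maxima on adjacent planes within
#'   `min_separation_px` to the brightest one, so each molecule is counted
#'   once per stack (densities divide by the full stack depth).
#' @return List of class `spot_call_params`.
#' @export
spot_call_params <- function(log_sigma_px = 1.3, detection_threshold = NULL,
                             min_separation_px = 3, z_merge = TRUE) {
  stopifnot(log_sigma_px > 0, min_separation_px > 0,
            is.null(detection_threshold) || detection_threshold > 0)
  structure(list(log_sigma_px = log_sigma_px,
                 detection_threshold = detection_threshold,
                 min_separation_px = min_separation_px, z_merge = z_merge),
            class = "spot_call_params")
}

## scale-normalized, sign-flipped LoG response (bright blobs -> positive)
log_response <- function(plane, sigma) {
  sm <- EBImage::gblur(plane, sigma = sigma)
  -sigma^2 * laplacian(as.matrix(sm))
}

#' Detect diffraction-limited spots in an image stack
#'
#' Per plane, the image is band-pass filtered with a scale-normalized
#' Laplacian of Gaussian; local maxima above the detection threshold are
#' kept, suppressed greedily (brightest first) within `min_separation_px`,
#' optionally merged across adjacent planes, and localized to sub-pixel
#' precision by a quadratic fit of the 3 x 3 response neighborhood.
#'
#' @param stack Numeric array `height x width x planes` (a matrix is treated
#'   as a single plane).
#' @param params [spot_call_params()].
#' @param field_id,channel Identifiers stamped on the output rows.
#' @return A [spot_table()] with columns `field_id`, `channel`, `x_px`,
#'   `y_px`, `plane` (0-based) and `intensity` (LoG response at the peak).
#' @export
detect_spots <- function(stack, params = spot_call_params(),
                         field_id = "fov1", channel = "spots") {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (length(dim(stack)) != 3L || any(dim(stack) == 0L)) {
    stop("stack must be a height x width x planes array with >= 1 plane")
  }
  n_planes <- dim(stack)[3]
  resp <- lapply(seq_len(n_planes), function(p) {
    log_response(stack[, , p], params$log_sigma_px)
  })
  thr <- params$detection_threshold
  if (is.null(thr)) {
    # histogram knee of the response, floored at a robust noise ceiling so
    # the knee cannot land inside the background-fluctuation tail
    all_resp <- unlist(resp)
    thr <- max(knee_threshold(all_resp),
               stats::median(all_resp) + 8 * stats::mad(all_resp))
  }
  cand <- do.call(rbind, lapply(seq_len(n_planes), function(p) {
    r <- resp[[p]]
    sel <- which(local_maxima(r) & r > thr, arr.ind = TRUE)
    if (nrow(sel) == 0L) return(NULL)
    cbind(row = sel[, 1], col = sel[, 2], plane = p, value = r[sel])
  }))
  empty <- spot_table(data.frame(field_id = character(0), channel = character(0),
                                 x_px = numeric(0), y_px = numeric(0),
                                 plane = integer(0), intensity = numeric(0)))
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand[, "value"]), , drop = FALSE]
  keep <- logical(nrow(cand))
  acc_r <- numeric(0); acc_c <- numeric(0); acc_p <- integer(0)
  min_sep2 <- params$min_separation_px^2
  for (i in seq_len(nrow(cand))) {
    if (length(acc_r)) {
      d2 <- (acc_r - cand[i, "row"])^2 + (acc_c - cand[i, "col"])^2
      same_plane <- acc_p == cand[i, "plane"]
      near_z <- if (params$z_merge) abs(acc_p - cand[i, "plane"]) <= 1L else same_plane
      if (any(d2 <= min_sep2 & near_z)) next
    }
    keep[i] <- TRUE
    acc_r <- c(acc_r, cand[i, "row"]); acc_c <- c(acc_c, cand[i, "col"])
    acc_p <- c(acc_p, cand[i, "plane"])
  }
  cand <- cand[keep, , drop = FALSE]
  # sub-pixel refinement: 1-D parabola through the 3-point response profile
  sub <- function(lo, c0, hi) {
    den <- lo - 2 * c0 + hi
    off <- ifelse(abs(den) < 1e-12, 0, 0.5 * (lo - hi) / den)
    pmin(0.5, pmax(-0.5, off))
  }
  xs <- numeric(nrow(cand)); ys <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- resp[[cand[i, "plane"]]]
    ri <- cand[i, "row"]; ci <- cand[i, "col"]
    dy <- if (ri > 1 && ri < nrow(r)) sub(r[ri - 1, ci], r[ri, ci], r[ri + 1, ci]) else 0
    dx <- if (ci > 1 && ci < ncol(r)) sub(r[ri, ci - 1], r[ri, ci], r[ri, ci + 1]) else 0
    xs[i] <- ci - 1 + dx
    ys[i] <- ri - 1 + dy
  }
  out <- data.frame(field_id = field_id, channel = channel,
                    x_px = xs, y_px = ys,
                    plane = as.integer(cand[, "plane"]) - 1L,
                    intensity = cand[, "value"], stringsAsFactors = FALSE)
  spot_table(out[order(-out$intensity), ])
}

#' Match detections to ground-truth spots
#'
#' Greedy one-to-one nearest-pair matching in (x, y) within a tolerance:
#' candidate pairs are ranked by distance and accepted while both members
#' are unmatched.  Unmatched detections are false positives; unmatched
#' truth spots are false negatives.
#'
#' @param detected,truth Data frames with `x_px`, `y_px` columns.
#' @param tolerance_px Maximum match distance.
#' @return List: `precision`, `recall`, `f1`, `n_matched`, `n_detected`,
#'   `n_truth`.
#' @export
match_spots <- function(detected, truth, tolerance_px = 2) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L) {
    return(list(precision = if (nd == 0L) NA_real_ else 0,
                recall = if (nt == 0L) NA_real_ else 0,
                f1 = 0, n_matched = 0L, n_detected = nd, n_truth = nt))
  }
  d2 <- outer(detected$x_px, truth$x_px, "-")^2 +
    outer(detected$y_px, truth$y_px, "-")^2
  pairs <- which(d2 <= tolerance_px^2, arr.ind = TRUE)
  n_matched <- 0L
  if (nrow(pairs)) {
    ord <- order(d2[pairs])
    used_d <- logical(nd); used_t <- logical(nt)
    for (k in ord) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE; used_t[j] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  precision <- n_matched / nd
  recall <- n_matched / nt
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_matched = n_matched, n_detected = nd, n_truth = nt)
}
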
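# Shannon-entropy diversity of pseudo-cell expression levels, neighbor and
# distance statistics of the expression topography, inter-regional
# variability and two-channel single-cell co-expression.
#
# "Expression level" is the distinct integer dot count of a thresholded
# pseudo-cell: the entropy sums over the observed levels l with p_l the
# fraction of passing pseudo-cells at that level.

## entropy machinery shared by local and global diversity
shannon_levels <- function(counts, dot_threshold) {
  counts <- counts[counts >= dot_threshold]
  n <- length(counts)
  if (n == 0L) {
    return(list(L = 0L, H = NA_real_, H_norm = NA_real_, n = 0L, flagged = TRUE))
  }
  p <- as.numeric(table(counts)) / n
  L <- length(p)
  H <- -sum(p * log2(p))
  H_norm <- if (L <= 1L) 0 else H / log2(L)
  list(L = L, H = H, H_norm = H_norm, n = n, flagged = FALSE)
}

#' Local (per-field) Shannon diversity of pseudo-cell expression
#'
#' For one field, the diversity of the distinct dot counts among pseudo-cells
#' passing the channel's dot threshold: `H = -sum p_l log2 p_l` over the
#' observed levels, normalized as `H / log2 L` (defined as 0 when only one
#' level is present).  The conventional thresholds are >= 3 dots for HER2
#' and >= 1 dot for ER.
#'
#' @param grid A [grid_counts()] result.
#' @param channel Channel name.
#' @param dot_threshold Minimum dots per pseudo-cell.
#' @return List: `L` (number of levels), `H` (bits), `H_norm` (in `[0, 1]`),
#'   `n` (passing pseudo-cells), `flagged` (TRUE when none pass).
#' @examples
#' # counts {3,3,5,7}: p = (1/2, 1/4, 1/4), H = 1.5 bits, H_norm = 1.5/log2(3)
#' @export
local_diversity <- function(grid, channel, dot_threshold = 3L) {
  stopifnot(inherits(grid, "pseudocell_grid"))
  cnt <- if (channel %in% names(grid$counts)) as.vector(grid$counts[[channel]])
  else integer(grid$g^2)
  shannon_levels(cnt, dot_threshold)
}

#' Global (case-level) Shannon diversity
#'
#' Identical computation on the pooled multiset of passing pseudo-cell
#' counts from all fields of the case.
#'
#' @param grids List of [grid_counts()] results (the case's fields).
#' @inheritParams local_diversity
#' @return As [local_diversity()].
#' @export
global_diversity <- function(grids, channel, dot_threshold = 3L) {
  if (inherits(grids, "pseudocell_grid")) grids <- list(grids)
  cnt <- unlist(lapply(grids, function(gr) {
    if (channel %in% names(gr$counts)) as.vector(gr$counts[[channel]])
    else integer(gr$g^2)
  }))
  shannon_levels(cnt, dot_threshold)
}

#' Mean and coefficient of variation of local diversity across fields
#'
#' @param h_norm Vector of per-field normalized local diversity indices
#'   (NAs from fields with no passing pseudo-cells are dropped).
#' @return List: `mean`, `cv` (sample sd / mean), `n_fields`, `flagged`
#'   (TRUE when fewer than 2 usable fields or zero mean).
#' @export
diversity_dispersion <- function(h_norm) {
  h <- h_norm[!is.na(h_norm)]
  if (length(h) < 2L || mean(h) == 0) {
    return(list(mean = if (length(h)) mean(h) else NA_real_, cv = NA_real_,
                n_fields = length(h), flagged = TRUE))
  }
  list(mean = mean(h), cv = stats::sd(h) / mean(h), n_fields = length(h),
       flagged = FALSE)
}

#' Absolute count differences between adjacent pseudo-cells
#'
#' All unordered pairs of 8-neighborhood-adjacent pseudo-cells in which both
#' members pass the dot threshold; border pseudo-cells contribute only their
#' existing neighbors.
#'
#' @inheritParams local_diversity
#' @return List: `diffs` (vector of |count_i - count_j|), `mean`, `n_pairs`.
#' @export
neighbor_differences <- function(grid, channel, dot_threshold = 3L) {
  stopifnot(inherits(grid, "pseudocell_grid"))
  m <- grid$counts[[channel]]
  if (is.null(m)) m <- matrix(0L, grid$g, grid$g)
  pass <- m >= dot_threshold
  g <- grid$g
  diffs <- numeric(0)
  # four direction offsets cover each unordered 8-neighbor pair exactly once
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(g - dr)
    c1 <- if (dc >= 0) seq_len(g - dc) else (1 - dc):g
    a <- m[r1, c1, drop = FALSE]
    b <- m[r1 + dr, c1 + dc, drop = FALSE]
    ok <- pass[r1, c1, drop = FALSE] & pass[r1 + dr, c1 + dc, drop = FALSE]
    diffs <- c(diffs, abs(a - b)[ok])
  }
  list(diffs = diffs, mean = if (length(diffs)) mean(diffs) else NA_real_,
       n_pairs = length(diffs))
}

## per-field pair vectors: Euclidean distance (um) and |count difference|
pair_vectors_grid <- function(grid, channel, dot_threshold, use_density = FALSE) {
  m <- grid$counts[[channel]]
  if (is.null(m)) return(NULL)
  pass <- which(m >= dot_threshold, arr.ind = TRUE)
  if (nrow(pass) < 2L) return(NULL)
  meta <- grid$meta
  side_x_um <- meta$width_px / grid$g * meta$pixel_size_um
  side_y_um <- meta$height_px / grid$g * meta$pixel_size_um
  cx <- (pass[, "col"] - 0.5) * side_x_um
  cy <- (pass[, "row"] - 0.5) * side_y_um
  val <- m[pass]
  if (use_density) val <- val / (grid$cell_area_um2 * grid$depth_um)
  ij <- utils::combn(nrow(pass), 2L)
  list(dist = sqrt((cx[ij[1, ]] - cx[ij[2, ]])^2 + (cy[ij[1, ]] - cy[ij[2, ]])^2),
       diff = abs(val[ij[1, ]] - val[ij[2, ]]))
}

pair_vectors_cells <- function(cells, channel, dot_threshold, use_density = FALSE) {
  cc <- cells[cells$channel == channel & cells$count >= dot_threshold, , drop = FALSE]
  out <- list(dist = numeric(0), diff = numeric(0))
  for (f in unique(cc$field_id)) {
    s <- cc[cc$field_id == f, , drop = FALSE]
    if (nrow(s) < 2L) next
    ij <- utils::combn(nrow(s), 2L)
    val <- if (use_density) s$density else s$count
    out$dist <- c(out$dist, sqrt((s$centroid_x_um[ij[1, ]] - s$centroid_x_um[ij[2, ]])^2 +
                                   (s$centroid_y_um[ij[1, ]] - s$centroid_y_um[ij[2, ]])^2))
    out$diff <- c(out$diff, abs(val[ij[1, ]] - val[ij[2, ]]))
  }
  out
}

#' Distance-expression scaling within fields of a case
#'
#' For every field, all pairs of thresholded units (pseudo-cells or
#' segmented cells) contribute their Euclidean separation (um, pseudo-cell
#' centers or cell centroids) and absolute expression difference (dot
#' counts by default, densities with `use_density = TRUE`).  Pairs never
#' cross fields.  The per-case concatenated vectors are correlated with
#' [rank_correlation()].
#'
#' @param grids List of [grid_counts()] results (for `unit = "pseudocell"`).
#' @param cells A [score_cells()] table (for `unit = "cell"`).
#' @param channel Channel name.
#' @param dot_threshold Minimum dots per unit.
#' @param unit `"pseudocell"` or `"cell"`.
#' @param use_density Use density instead of count differences (identical
#'   rank correlation for pseudo-cells, which share one volume).
#' @return List: `rho`, `p.value`, `n_pairs`, `flagged` (TRUE when fewer
#'   than 2 passing units in every field or zero-variance differences).
#' @export
distance_expression_scaling <- function(grids = NULL, cells = NULL, channel,
                                        dot_threshold = 3L,
                                        unit = c("pseudocell", "cell"),
                                        use_density = FALSE) {
  unit <- match.arg(unit)
  vecs <- if (unit == "pseudocell") {
    if (inherits(grids, "pseudocell_grid")) grids <- list(grids)
    parts <- Filter(Negate(is.null),
                    lapply(grids, pair_vectors_grid, channel, dot_threshold, use_density))
    list(dist = unlist(lapply(parts, `[[`, "dist")),
         diff = unlist(lapply(parts, `[[`, "diff")))
  } else {
    pair_vectors_cells(cells, channel, dot_threshold, use_density)
  }
  if (length(vecs$dist) < 3L) {
    return(list(rho = NA_real_, p.value = NA_real_, n_pairs = length(vecs$dist),
                flagged = TRUE))
  }
  rc <- rank_correlation(vecs$dist, vecs$diff)
  list(rho = rc$rho, p.value = rc$p.value, n_pairs = rc$n, flagged = rc$flagged)
}

#' Inter-regional variability of single-cell densities
#'
#' Mean single-cell transcript density per field of view, summarized as a
#' coefficient of variation across the case's fields.
#'
#' @param cells A [score_cells()] table pooled over the case's fields.
#' @param channel Channel name.
#' @param field_ids Optional full list of the case's fields; fields absent
#'   from `cells` (no segmented cells) are then reported as skipped.
#' @return List: `cv`, `field_means` (named per field), `n_fields`,
#'   `skipped_fields` (fields with no cells), `flagged`.
#' @export
interregional_variability <- function(cells, channel, field_ids = NULL) {
  cc <- cells[cells$channel == channel, , drop = FALSE]
  means <- tapply(cc$density, cc$field_id, mean)
  means <- stats::setNames(as.numeric(means), names(means))
  skipped <- if (is.null(field_ids)) character(0) else
    setdiff(as.character(field_ids), names(means))
  means <- means[!is.na(means)]
  if (length(means) < 2L || mean(means) == 0) {
    return(list(cv = NA_real_, field_means = means, n_fields = length(means),
                skipped_fields = skipped, flagged = TRUE))
  }
  list(cv = stats::sd(means) / mean(means), field_means = means,
       n_fields = length(means), skipped_fields = skipped, flagged = FALSE)
}

#' Single-cell co-expression of two channels
#'
#' Per segmented cell, the densities of the two channels (counts below a
#' channel's dot threshold are zeroed, mirroring the per-cell scoring
#' convention: 0 dots for HER2, 1 dot for ER) are correlated across all
#' cells of the case with [rank_correlation()].
#'
#' @param cells A [score_cells()] table.
#' @param channel_a,channel_b Channel names.
#' @param thresholds Named numeric: dot threshold per channel (defaults 0).
#' @return List: `rho`, `p.value`, `n_cells`, `table` (per-cell densities),
#'   `flagged`.
#' @export
coexpression <- function(cells, channel_a, channel_b, thresholds = NULL) {
  thr <- function(ch) {
    if (!is.null(thresholds) && ch %in% names(thresholds)) thresholds[[ch]] else 0
  }
  pull <- function(ch) {
    cc <- cells[cells$channel == ch, c("cell_id", "count", "density")]
    cc$density[cc$count < thr(ch)] <- 0
    stats::setNames(cc$density, cc$cell_id)
  }
  da <- pull(channel_a); db <- pull(channel_b)
  ids <- intersect(names(da), names(db))
  tab <- data.frame(cell_id = ids, density_a = unname(da[ids]),
                    density_b = unname(db[ids]), stringsAsFactors = FALSE)
  rc <- rank_correlation(tab$density_a, tab$density_b)
  list(rho = rc$rho, p.value = rc$p.value, n_cells = nrow(tab), table = tab,
       flagged = rc$flagged)
}

#' Nucleus areas of high- vs low-expressing cells
#'
#' Splits the segmented cells of a case at a density cutoff and compares
#' the (undilated) nucleus areas of the two strata with [compare_groups()].
#'
#' @param cells A [score_cells()] table.
#' @param channel Channel name.
#' @param density_split Density cutoff (dots/um^3) defining "high".
#' @return List: `areas_high`, `areas_low`, `U`, `p.value`, `flagged`
#'   (TRUE when either stratum is empty).
#' @export
nucleus_area_contrast <- function(cells, channel, density_split) {
  cc <- cells[cells$channel == channel, , drop = FALSE]
  hi <- cc$density > density_split
  if (!any(hi) || all(hi)) {
    return(list(areas_high = cc$nucleus_area_um2[hi],
                areas_low = cc$nucleus_area_um2[!hi],
                U = NA_real_, p.value = NA_real_, flagged = TRUE))
  }
  cmp <- compare_groups(cc$nucleus_area_um2[hi], cc$nucleus_area_um2[!hi])
  list(areas_high = cc$nucleus_area_um2[hi], areas_low = cc$nucleus_area_um2[!hi],
       U = cmp$U, p.value = cmp$p.value, flagged = FALSE)
}
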
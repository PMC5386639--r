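# Transcript-density scoring: pseudo-cell grids, segmented cells and
# structure-tensor nuclei regions.
#
# All densities are volumetric (dots/um^3).  The imaging depth of a field is
# (n_planes - 1) * plane_spacing_um: cells and pseudo-cells are treated as
# prisms of that height because the tissue is only sampled between the first
# and last focal plane.

#' Count spots in a regular grid of pseudo-cells
#'
#' Splits the field into a `g x g` grid of square pseudo-cells with exact
#' fractional-pixel boundaries (side `width_px / g`) and counts the spots of
#' each channel per pseudo-cell.  A spot at (x, y) goes to column
#' `floor(x / (width_px / g))` and row `floor(y / (height_px / g))`; a spot
#' sitting exactly on an internal boundary therefore goes to the higher
#' index, and the far edge clamps to the last pseudo-cell.
#'
#' @param spots A [spot_table()] (all rows must belong to `meta`'s field).
#' @param meta The owning [fov_meta()].
#' @param g Grid order (the grids used in practice are 9-16, any `g >= 1`
#'   is accepted).
#' @param channels Channels to tabulate; default all channels in `spots`.
#' @return Object of class `pseudocell_grid`: a list with `field_id`, `g`,
#'   `counts` (named list of `g x g` integer matrices, rows = grid rows),
#'   pseudo-cell geometry (`cell_side_um`, `cell_area_um2`, `depth_um`) and
#'   `densities` (filled by [pseudocell_densities()]).
#' @examples
#' m <- fov_meta("f", 1024, 1024)
#' s <- spot_table(data.frame(field_id = "f", channel = "HER2",
#'                            x_px = 300, y_px = 10, plane = 0))
#' which(grid_counts(s, m, g = 4)$counts$HER2 == 1)  # row 1, column 2
#' @export
grid_counts <- function(spots, meta, g = 13L, channels = NULL) {
  stopifnot(inherits(meta, "fov_meta"), g >= 1)
  g <- as.integer(g)
  if (nrow(spots) > 0 && any(spots$field_id != meta$field_id)) {
    stop("spots from a different field than ", meta$field_id)
  }
  if (is.null(channels)) channels <- sort(unique(spots$channel))
  if (length(channels) == 0L) channels <- character(0)
  side_x <- meta$width_px / g
  side_y <- meta$height_px / g
  counts <- lapply(channels, function(ch) {
    s <- spots[spots$channel == ch, , drop = FALSE]
    col <- pmin(floor(s$x_px / side_x), g - 1L) + 1L
    row <- pmin(floor(s$y_px / side_y), g - 1L) + 1L
    m <- matrix(0L, g, g)
    if (nrow(s)) {
      tab <- table(factor(row, levels = 1:g), factor(col, levels = 1:g))
      m <- matrix(as.integer(tab), g, g)
    }
    m
  })
  names(counts) <- channels
  structure(list(
    field_id = meta$field_id, g = g, counts = counts,
    cell_side_um = side_x * meta$pixel_size_um,
    cell_area_um2 = (side_x * meta$pixel_size_um) * (side_y * meta$pixel_size_um),
    depth_um = meta$depth_um, meta = meta, densities = NULL
  ), class = "pseudocell_grid")
}

#' Convert pseudo-cell counts to volumetric densities
#'
#' density = count / ((n_planes - 1) * plane_spacing_um * pseudo-cell area).
#'
#' @param grid A [grid_counts()] result.
#' @return The grid with `densities` (dots/um^3) filled in.
#' @export
pseudocell_densities <- function(grid) {
  stopifnot(inherits(grid, "pseudocell_grid"))
  vol <- grid$cell_area_um2 * grid$depth_um
  grid$densities <- lapply(grid$counts, function(m) m / vol)
  grid
}

#' Case-level smFISH score from pseudo-cell grids
#'
#' The smFISH score of a case is the mean transcript density over all its
#' pseudo-cells, pooled across fields of view.  A dot threshold suppresses
#' background: with `policy = "exclude"` (default) pseudo-cells whose count
#' is below the threshold are dropped from the mean; with `policy = "zero"`
#' they enter the mean with density 0.
#'
#' @param grids List of [pseudocell_grid]s (one per field of the case).
#' @param channel Channel name.
#' @param dot_threshold Minimum dots per pseudo-cell (0-3 by convention).
#' @param policy `"exclude"` or `"zero"`.
#' @return List: `score` (dots/um^3; 0 when no pseudo-cell passes, with
#'   `flagged = TRUE`), `n_pseudocells`, `n_passing`, `flagged`.
#' @export
case_score <- function(grids, channel, dot_threshold = 3L,
                       policy = c("exclude", "zero")) {
  policy <- match.arg(policy)
  if (length(grids) == 0L) stop("no fields: cannot compute a case score")
  if (inherits(grids, "pseudocell_grid")) grids <- list(grids)
  counts <- unlist(lapply(grids, function(gr) {
    if (!channel %in% names(gr$counts))
      return(rep(0L, gr$g^2))
    as.vector(gr$counts[[channel]])
  }))
  dens <- unlist(lapply(grids, function(gr) {
    gr <- if (is.null(gr$densities)) pseudocell_densities(gr) else gr
    if (!channel %in% names(gr$densities)) return(rep(0, gr$g^2))
    as.vector(gr$densities[[channel]])
  }))
  pass <- counts >= dot_threshold
  if (!any(pass)) {
    return(list(score = 0, n_pseudocells = length(counts), n_passing = 0L,
                flagged = TRUE))
  }
  score <- if (policy == "exclude") mean(dens[pass]) else
    sum(dens[pass]) / length(dens)
  list(score = score, n_pseudocells = length(counts),
       n_passing = sum(pass), flagged = FALSE)
}

#' Dilate a nucleus outline into an approximate cell boundary
#'
#' Euclidean round-join buffer of the polygon by `margin_px`, optionally
#' clipped to the field bounds (spots cannot exist outside the field, so the
#' clipped area is the one relevant for densities).
#'
#' @param outline A [cell_outline()] (or bare vertex matrix).
#' @param margin_px Dilation margin in pixels; defaults to the outline's own
#'   `dilation_margin_px`.
#' @param meta Optional [fov_meta()]; when given, the result is clipped to
#'   `[0, width_px] x [0, height_px]`.
#' @return Vertex matrix of the dilated (and possibly clipped) polygon.
#' @export
dilate_outline <- function(outline, margin_px = NULL, meta = NULL) {
  poly <- if (inherits(outline, "cell_outline")) outline$vertices else as.matrix(outline)
  if (is.null(margin_px)) {
    margin_px <- if (inherits(outline, "cell_outline")) outline$dilation_margin_px else 0
  }
  out <- offset_polygon(poly, margin_px)
  if (!is.null(meta)) {
    out <- clip_polygon_rect(out, c(0, meta$width_px), c(0, meta$height_px))
  }
  out
}

#' Assign spots to (dilated) segmented cells
#'
#' A spot belongs to a cell when it falls inside the cell's dilated
#' footprint, i.e. inside the nucleus polygon or within `margin_px` of its
#' boundary.  When dilated footprints overlap, the spot goes to the cell
#' whose undilated nucleus boundary is nearest (ties to the
#' lexicographically smallest `cell_id`).  Spots in no footprint (stroma)
#' stay unassigned.
#'
#' @param spots A [spot_table()] restricted to one field.
#' @param outlines List of [cell_outline()]s of that field.
#' @param margin_px Dilation margin; defaults to each outline's own margin.
#' @return `spots` with a `cell_id` column (`NA` = unassigned).
#' @export
assign_spots_to_cells <- function(spots, outlines, margin_px = NULL) {
  if (inherits(outlines, "cell_outline")) outlines <- list(outlines)
  n <- nrow(spots)
  cell_ids <- vapply(outlines, `[[`, character(1), "cell_id")
  o <- order(cell_ids)
  outlines <- outlines[o]; cell_ids <- cell_ids[o]
  best_cell <- rep(NA_character_, n)
  best_dist <- rep(Inf, n)
  x <- spots$x_px; y <- spots$y_px
  for (k in seq_along(outlines)) {
    poly <- outlines[[k]]$vertices
    m <- if (is.null(margin_px)) outlines[[k]]$dilation_margin_px else margin_px
    cand <- which(x >= min(poly[, 1]) - m & x <= max(poly[, 1]) + m &
                    y >= min(poly[, 2]) - m & y <= max(poly[, 2]) + m)
    if (!length(cand)) next
    d <- dist_to_polygon(x[cand], y[cand], poly)
    member <- d <= m | points_in_polygon(x[cand], y[cand], poly)
    hit <- cand[member & d < best_dist[cand]]
    # strict '<' plus ascending cell_id order implements the tie -> lowest id
    best_dist[hit] <- d[member & d < best_dist[cand]]
    best_cell[hit] <- cell_ids[k]
  }
  spots$cell_id <- best_cell
  spots
}

#' Per-cell transcript counts and densities
#'
#' Assigns spots to dilated cells and computes, per cell and channel, the
#' transcript count and volumetric density
#' `count / (footprint area (um^2) * (n_planes - 1) * plane_spacing_um)`.
#' The prism base is the dilated footprint clipped at the field borders by
#' default (`area = "dilated"`), since that is the region spots are counted
#' in; `area = "nucleus"` uses the undilated polygon instead.
#'
#' @param spots A [spot_table()] of one field.
#' @param outlines List of [cell_outline()]s of that field.
#' @param meta The field's [fov_meta()].
#' @param margin_px Dilation margin override (default: each outline's own).
#' @param channels Channels to report (default: those present in `spots`).
#' @param area Prism base: `"dilated"` (default) or `"nucleus"`.
#' @return Data frame with one row per cell x channel: `cell_id`,
#'   `field_id`, `channel`, `count`, `density`, `nucleus_area_um2`,
#'   `footprint_area_um2`, `centroid_x_um`, `centroid_y_um`,
#'   `dilation_margin_px`.
#' @export
score_cells <- function(spots, outlines, meta, margin_px = NULL,
                        channels = NULL, area = c("dilated", "nucleus")) {
  area <- match.arg(area)
  stopifnot(inherits(meta, "fov_meta"))
  if (inherits(outlines, "cell_outline")) outlines <- list(outlines)
  if (is.null(channels)) channels <- sort(unique(spots$channel))
  px_um <- meta$pixel_size_um
  assigned <- assign_spots_to_cells(spots, outlines, margin_px)
  res <- lapply(outlines, function(o) {
    m <- if (is.null(margin_px)) o$dilation_margin_px else margin_px
    foot <- if (area == "dilated") dilate_outline(o, m, meta) else o$vertices
    foot_area_um2 <- polygon_area(foot) * px_um^2
    cen <- polygon_centroid(o$vertices) * px_um
    vol <- foot_area_um2 * meta$depth_um
    cnt <- vapply(channels, function(ch) {
      sum(assigned$cell_id == o$cell_id & assigned$channel == ch, na.rm = TRUE)
    }, numeric(1))
    data.frame(cell_id = o$cell_id, field_id = o$field_id, channel = channels,
               count = as.integer(cnt), density = cnt / vol,
               nucleus_area_um2 = polygon_area(o$vertices) * px_um^2,
               footprint_area_um2 = foot_area_um2,
               centroid_x_um = cen[1], centroid_y_um = cen[2],
               dilation_margin_px = m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Case-level smFISH score from segmented cells
#'
#' Mean single-cell density over all cells of a case whose transcript count
#' meets the dot threshold (mirroring [case_score()] for pseudo-cells).
#'
#' @param cells A [score_cells()] table pooled over the case's fields.
#' @param channel Channel name.
#' @param dot_threshold Minimum dots per cell.
#' @param policy `"exclude"` or `"zero"` (see [case_score()]).
#' @return List: `score`, `n_cells`, `n_passing`, `flagged`.
#' @export
cell_case_score <- function(cells, channel, dot_threshold = 0L,
                            policy = c("exclude", "zero")) {
  policy <- match.arg(policy)
  cc <- cells[cells$channel == channel, , drop = FALSE]
  if (nrow(cc) == 0L) stop("no cells for channel ", channel)
  pass <- cc$count >= dot_threshold
  if (!any(pass)) return(list(score = 0, n_cells = nrow(cc), n_passing = 0L,
                              flagged = TRUE))
  score <- if (policy == "exclude") mean(cc$density[pass]) else
    sum(cc$density[pass]) / nrow(cc)
  list(score = score, n_cells = nrow(cc), n_passing = sum(pass), flagged = FALSE)
}
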
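# Domain types, coordinate conventions and tabular/polygon I/O.
#
# Coordinate conventions used throughout the package:
#   * x = column, increasing rightward; y = row, increasing downward;
#     0-based, continuous, with pixel centers at integer coordinates.
#   * plane (focal plane) index is 0-based; physical z = plane * plane_spacing_um.

#' Field-of-view metadata
#'
#' Describes one imaged region: raster geometry, pixel size and the focal
#' plane stack.  The imaging depth used for all volumetric densities is
#' \code{(n_planes - 1) * plane_spacing_um}, i.e. the span between the first
#' and last acquired plane.
#'
#' @param field_id Identifier (coerced to character).
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_nm Lateral pixel size in nanometers.
#' @param n_planes Number of focal planes (>= 2).
#' @param plane_spacing_um Spacing between adjacent planes in micrometers.
#' @param case_id Identifier of the owning case (character), or `NA`.
#' @return An object of class `fov_meta`.
#' @examples
#' fov_meta("fov1")                       # 1024 x 1024 px, 125 nm/px, 5 planes
#' fov_meta("fov2", n_planes = 9)$depth_um
#' @export
fov_meta <- function(field_id, width_px = 1024L, height_px = 1024L,
                     pixel_size_nm = 125, n_planes = 5L,
                     plane_spacing_um = 0.4, case_id = NA_character_) {
  stopifnot(width_px >= 1, height_px >= 1, pixel_size_nm > 0,
            n_planes >= 2, plane_spacing_um > 0)
  structure(list(
    field_id = as.character(field_id),
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_nm = pixel_size_nm,
    n_planes = as.integer(n_planes), plane_spacing_um = plane_spacing_um,
    case_id = as.character(case_id),
    pixel_size_um = pixel_size_nm / 1000,
    depth_um = (n_planes - 1) * plane_spacing_um
  ), class = "fov_meta")
}

#' @export
print.fov_meta <- function(x, ...) {
  cat(sprintf("<fov_meta> %s: %d x %d px, %.0f nm/px, %d planes / %.2f um (case %s)\n",
              x$field_id, x$width_px, x$height_px, x$pixel_size_nm,
              x$n_planes, x$plane_spacing_um, x$case_id))
  invisible(x)
}

#' Build a field-of-view registry from a list of `fov_meta` objects
#'
#' @param metas List of [fov_meta()] objects.
#' @return Named list keyed by `field_id`, class `fov_registry`.
#' @export
fov_registry <- function(metas) {
  if (inherits(metas, "fov_meta")) metas <- list(metas)
  stopifnot(all(vapply(metas, inherits, logical(1), "fov_meta")))
  ids <- vapply(metas, `[[`, character(1), "field_id")
  if (anyDuplicated(ids)) stop("duplicate field_id in registry")
  structure(stats::setNames(metas, ids), class = "fov_registry")
}

spot_columns <- c("field_id", "channel", "x_px", "y_px", "plane")

#' Construct and validate a spot table
#'
#' A spot table is a data frame of per-molecule detections with columns
#' `field_id`, `channel`, `x_px`, `y_px`, `plane` and optionally `intensity`.
#' Coordinates must satisfy `0 <= x_px < width_px`, `0 <= y_px < height_px`
#' and `0 <= plane < n_planes` of the owning field.
#'
#' @param df Data frame with the columns above.
#' @param registry A [fov_registry()] (or single [fov_meta()]) used for
#'   bound checks; `NULL` skips the coordinate validation.
#' @return The validated data frame, class `c("spot_table", "data.frame")`.
#' @export
spot_table <- function(df, registry = NULL) {
  miss <- setdiff(spot_columns, names(df))
  if (length(miss)) stop("spot table is missing columns: ", paste(miss, collapse = ", "))
  df$field_id <- as.character(df$field_id)
  df$channel <- as.character(df$channel)
  df$plane <- as.integer(df$plane)
  if (!is.null(registry)) {
    if (inherits(registry, "fov_meta")) registry <- fov_registry(list(registry))
    unknown <- setdiff(unique(df$field_id), names(registry))
    if (length(unknown)) stop("spots reference unknown field(s): ", paste(unknown, collapse = ", "))
    bad <- logical(nrow(df))
    for (fid in unique(df$field_id)) {
      m <- registry[[fid]]
      i <- df$field_id == fid
      bad[i] <- df$x_px[i] < 0 | df$x_px[i] >= m$width_px |
        df$y_px[i] < 0 | df$y_px[i] >= m$height_px |
        df$plane[i] < 0 | df$plane[i] >= m$n_planes
    }
    if (any(bad)) {
      stop("out-of-bounds spot coordinates in row(s): ",
           paste(utils::head(which(bad), 20), collapse = ", "))
    }
  }
  class(df) <- unique(c("spot_table", class(df)))
  df
}

#' Read / write spot tables (CSV)
#'
#' Comma-separated UTF-8 text with a mandatory header row.
#'
#' @param path File path.
#' @param registry Optional [fov_registry()] for coordinate validation.
#' @return [read_spot_table()] returns a validated spot table;
#'   [write_spot_table()] invisibly returns `path`.
#' @export
read_spot_table <- function(path, registry = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  spot_table(df, registry)
}

#' @rdname read_spot_table
#' @param spots A spot table.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.csv(as.data.frame(spots)[, intersect(c(spot_columns, "intensity"), names(spots))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Nucleus outline with dilation margin
#'
#' The polygon traces the DAPI-segmented nucleus boundary; the margin is the
#' uniform outward dilation (in pixels) used to approximate the whole cell
#' when assigning cytoplasmic transcripts.
#'
#' @param cell_id,field_id Identifiers.
#' @param vertices n x 2 numeric matrix of (x_px, y_px) vertices, n >= 3.
#' @param dilation_margin_px Non-negative dilation margin in pixels.
#' @return An object of class `cell_outline`.
#' @export
cell_outline <- function(cell_id, field_id, vertices, dilation_margin_px = 0) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("outline needs >= 3 vertices (cell ", cell_id, ")")
  colnames(vertices) <- c("x", "y")
  if (polygon_area(vertices) <= 0) stop("outline has zero area (cell ", cell_id, ")")
  if (!polygon_is_simple(vertices)) stop("outline polygon self-intersects (cell ", cell_id, ")")
  stopifnot(dilation_margin_px >= 0)
  structure(list(cell_id = as.character(cell_id), field_id = as.character(field_id),
                 vertices = vertices, dilation_margin_px = dilation_margin_px),
            class = "cell_outline")
}

#' Read / write cell outlines (JSON)
#'
#' One JSON record per cell, with fields `cell_id`, `field_id`,
#' `dilation_margin_px` and `vertices` (array of [x, y] pairs).  GeoJSON-style
#' records (`geometry: {type: "Polygon", coordinates: [[...]]}`) are also
#' accepted on input; a closing vertex equal to the first is dropped.
#'
#' @param path File path.
#' @return [read_cell_outlines()] returns a list of [cell_outline()] objects.
#' @export
read_cell_outlines <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    if (!is.null(r$geometry)) {
      if (!identical(r$geometry$type, "Polygon")) stop("unsupported geometry type: ", r$geometry$type)
      v <- do.call(rbind, lapply(r$geometry$coordinates[[1]], unlist))
    } else {
      v <- do.call(rbind, lapply(r$vertices, unlist))
    }
    if (nrow(v) >= 2L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    margin <- if (is.null(r$dilation_margin_px)) 0 else r$dilation_margin_px
    cell_outline(r$cell_id, r$field_id, v, margin)
  })
}

#' @rdname read_cell_outlines
#' @param outlines List of [cell_outline()] objects.
#' @export
write_cell_outlines <- function(outlines, path) {
  if (inherits(outlines, "cell_outline")) outlines <- list(outlines)
  recs <- lapply(outlines, function(o) {
    list(cell_id = o$cell_id, field_id = o$field_id,
         dilation_margin_px = o$dilation_margin_px,
         vertices = lapply(seq_len(nrow(o$vertices)), function(i) unname(o$vertices[i, ])))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write field metadata and case tables (CSV)
#'
#' @param path File path.
#' @return [read_fov_meta()] returns a [fov_registry()];
#'   [read_case_table()] returns a data frame of case records.
#' @export
read_fov_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fov_registry(lapply(seq_len(nrow(df)), function(i) {
    with(df[i, ], fov_meta(field_id, width_px, height_px, pixel_size_nm,
                           n_planes, plane_spacing_um, case_id))
  }))
}

#' @rdname read_fov_meta
#' @param registry A [fov_registry()].
#' @export
write_fov_meta <- function(registry, path) {
  df <- do.call(rbind, lapply(registry, function(m) {
    data.frame(field_id = m$field_id, width_px = m$width_px, height_px = m$height_px,
               pixel_size_nm = m$pixel_size_nm, n_planes = m$n_planes,
               plane_spacing_um = m$plane_spacing_um, case_id = m$case_id)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_fov_meta
#' @export
read_case_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "her2_ihc", "her2_amplified", "er_percent", "pr_percent", "ki67_percent")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("case table is missing columns: ", paste(miss, collapse = ", "))
  df$her2_ihc <- as.character(df$her2_ihc)
  df
}

#' @rdname read_fov_meta
#' @param cases Case-record data frame.
#' @export
write_case_table <- function(cases, path) {
  utils::write.csv(cases, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive HER2/ER positivity from clinical reference labels
#'
#' HER2 positivity follows the clinical rule: immunohistochemistry (IHC)
#' score 3+, or score 2+ with HER2 amplification confirmed by DNA FISH.
#' ER positivity is >= 1\% of positive tumor nuclei at IHC.
#'
#' @param cases Data frame with columns `her2_ihc` (one of "0", "1+", "2+",
#'   "3+"), `her2_amplified` (logical) and `er_percent` (0-100).
#' @return The data frame with logical columns `her2_positive`, `er_positive`
#'   added (or overwritten).
#' @export
derive_positivity <- function(cases) {
  need <- c("her2_ihc", "her2_amplified", "er_percent")
  miss <- setdiff(need, names(cases))
  if (length(miss)) stop("missing label column(s): ", paste(miss, collapse = ", "))
  if (anyNA(cases[need])) stop("missing (NA) labels in: ", paste(need, collapse = ", "))
  ihc <- as.character(cases$her2_ihc)
  bad <- !ihc %in% c("0", "1+", "2+", "3+")
  if (any(bad)) stop("invalid her2_ihc value(s): ", paste(unique(ihc[bad]), collapse = ", "))
  stopifnot(all(cases$er_percent >= 0 & cases$er_percent <= 100))
  cases$her2_positive <- ihc == "3+" | (ihc == "2+" & cases$her2_amplified)
  cases$er_positive <- cases$er_percent >= 1
  cases
}

#' Derive the IHC-surrogate molecular subtype
#'
#' St. Gallen-style surrogate classification from ER/PR/HER2/Ki67:
#' triple-negative (ER-/PR-/HER2-), HER2 (ER-/HER2+), Luminal B/HER2-pos
#' (ER+/HER2+), Luminal B/HER2-neg (ER+/HER2- with Ki67 > 14\% and/or
#' PR < 20\%), else Luminal A.  "Ki67-low" means <= 14\%.
#'
#' @param cases Data frame with `her2_positive`, `er_positive` (see
#'   [derive_positivity()]), `pr_percent` and `ki67_percent`.
#' @return The data frame with a character column `subtype` added.
#' @export
derive_subtype <- function(cases) {
  if (!all(c("her2_positive", "er_positive") %in% names(cases))) {
    cases <- derive_positivity(cases)
  }
  stopifnot(all(cases$pr_percent >= 0 & cases$pr_percent <= 100),
            all(cases$ki67_percent >= 0 & cases$ki67_percent <= 100))
  pr_pos <- cases$pr_percent > 20
  cases$subtype <- ifelse(
    !cases$er_positive & !pr_pos & !cases$her2_positive, "Triple-neg",
    ifelse(!cases$er_positive & cases$her2_positive, "HER2",
    ifelse(cases$er_positive & cases$her2_positive, "LumB/HER2-pos",
    ifelse(cases$er_positive & !cases$her2_positive &
             (cases$ki67_percent > 14 | cases$pr_percent < 20),
           "LumB/HER2-neg", "LumA"))))
  cases
}
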
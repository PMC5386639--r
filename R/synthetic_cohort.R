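# Synthetic fields of view, cases and cohorts with known ground truth.
#
# The generator emulates the statistical structure that the scoring and
# heterogeneity analyses assume: 1024 x 1024 px fields at 125 nm/px with 5
# focal planes 0.4 um apart, ~19 +/- 10 convex tumor nuclei of ~65 um^2 per
# field, per-cell transcript counts drawn from a (possibly bimodal on/off)
# negative-binomial model, spot positions uniform inside the dilated cell
# footprint, a spot-free stromal margin, and a low uniform background spot
# rate.  Everything is reproducible from a single integer seed.

#' Per-channel expression model
#'
#' @param mode `"unimodal"` (all cells share one mean) or `"bimodal"`
#'   (a transcriptionally "on" subpopulation over an "off" background).
#' @param on_fraction Probability that a cell is "on" (ignored for unimodal).
#' @param on_mean_spots,off_mean_spots Mean transcript count per cell in each
#'   state; unimodal cells all use `on_mean_spots`.
#' @param overdispersion Negative-binomial overdispersion phi, so that
#'   Var = mu + phi * mu^2; `0` gives Poisson counts.
#' @return List of class `channel_model`.
#' @export
channel_model <- function(mode = c("unimodal", "bimodal"), on_fraction = 0.5,
                          on_mean_spots = 30, off_mean_spots = 1,
                          overdispersion = 0.2) {
  mode <- match.arg(mode)
  stopifnot(on_fraction >= 0, on_fraction <= 1, on_mean_spots >= 0,
            off_mean_spots >= 0, overdispersion >= 0)
  structure(list(mode = mode, on_fraction = on_fraction,
                 on_mean_spots = on_mean_spots, off_mean_spots = off_mean_spots,
                 overdispersion = overdispersion), class = "channel_model")
}

#' Simulation parameters for synthetic fields of view
#'
#' Defaults describe the imaging regime the package targets: 1024 x 1024 px
#' at 125 nm/px, 5 focal planes spaced 0.4 um, 19 +/- 10 tumor cells per
#' field with ~65 um^2 nuclei, a 20 px cell dilation margin, 20% stromal
#' (cell-free) field fraction and 0.001 background dots/um^3.
#'
#' @param width_px,height_px,pixel_size_nm,n_planes,plane_spacing_um Field
#'   geometry, see [fov_meta()].
#' @param n_cells_mean,n_cells_sd Cells per field (normal, rounded,
#'   truncated to `[1, n_cells_max]`).
#' @param n_cells_max Upper truncation of the cell count; the default 40
#'   keeps dart-throwing placement feasible for ~65 um^2 nuclei in a
#'   1024 px field while covering > 98% of the 19 +/- 10 distribution.
#' @param nucleus_area_mean_um2,nucleus_area_sd_um2 Nucleus area distribution
#'   (normal, truncated at >= 15 um^2).
#' @param channels Named list of [channel_model()]s, one per imaged gene.
#' @param spatial_pattern One of `"homogeneous"`, `"mixed"`, `"segregated"`,
#'   `"gradient"` (see [simulate_case()] for their interpretation).
#' @param n_clones Number of Voronoi clone patches for `"segregated"`.
#' @param stroma_fraction Fraction of the field width (left side) kept free
#'   of tumor cells.
#' @param background_spot_rate Spurious dots per um^3, uniform over the field.
#' @param dilation_margin_px Dilation margin within which a cell's spots are
#'   placed (and later re-assigned by the scoring code).
#' @param correlated_channels When `TRUE`, the per-cell on/off state is drawn
#'   once and shared by all bimodal channels, creating a subpopulation that
#'   co-expresses every channel (single-cell co-expression is positive);
#'   when `FALSE` (default) channels are independent.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(width_px = 1024L, height_px = 1024L, pixel_size_nm = 125,
                       n_planes = 5L, plane_spacing_um = 0.4,
                       n_cells_mean = 19, n_cells_sd = 10, n_cells_max = 40L,
                       nucleus_area_mean_um2 = 65, nucleus_area_sd_um2 = 15,
                       channels = list(HER2 = channel_model()),
                       spatial_pattern = c("mixed", "homogeneous", "segregated", "gradient"),
                       n_clones = 5L, stroma_fraction = 0.2,
                       background_spot_rate = 0.001, dilation_margin_px = 20,
                       correlated_channels = FALSE) {
  spatial_pattern <- match.arg(spatial_pattern)
  stopifnot(stroma_fraction >= 0, stroma_fraction < 1, background_spot_rate >= 0,
            all(vapply(channels, inherits, logical(1), "channel_model")))
  structure(as.list(environment()), class = "sim_params")
}

## negative-binomial counts with Poisson limit at zero overdispersion
rcounts <- function(n, mu, phi) {
  if (n == 0L) return(numeric(0))
  if (mu <= 0) return(numeric(n))
  as.numeric(if (phi <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / phi))
}

## random convex nucleus polygon of the given area, centered at the origin
gen_nucleus_poly <- function(area_px2) {
  n_v <- sample(8:14, 1L)
  ang <- sort(stats::runif(n_v, 0, 2 * pi))
  rad <- 1 + stats::runif(n_v, -0.15, 0.15)
  ratio <- stats::runif(1, 0.65, 1)
  th <- stats::runif(1, 0, pi)
  x0 <- rad * cos(ang) * sqrt(ratio)
  y0 <- rad * sin(ang) / sqrt(ratio)
  x <- x0 * cos(th) - y0 * sin(th)
  y <- x0 * sin(th) + y0 * cos(th)
  hull <- grDevices::chull(x, y)
  v <- cbind(x = x[hull], y = y[hull])
  v * sqrt(area_px2 / polygon_area(v))
}

## dart-throwing placement of non-overlapping nuclei in the tumor partition
place_nuclei <- function(n_cells, params, max_tries = 400L) {
  w <- params$width_px; h <- params$height_px
  px_um <- params$pixel_size_nm / 1000
  x_min <- params$stroma_fraction * w
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  polys <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      area_um2 <- max(15, stats::rnorm(1, params$nucleus_area_mean_um2,
                                       params$nucleus_area_sd_um2))
      poly <- gen_nucleus_poly(area_um2 / px_um^2)
      r <- sqrt(max(rowSums(poly^2)))
      if (x_min + r >= w - r || r >= h - r) next
      cx <- stats::runif(1, x_min + r, w - r)
      cy <- stats::runif(1, r, h - r)
      if (nrow(centers) > 0 &&
          any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) <= radii + r)) next
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
      polys[[i]] <- sweep(poly, 2, c(cx, cy), "+")
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible nucleus packing: placed ", i - 1L, " of ",
                      n_cells, " cells after ", max_tries, " tries each")
  }
  polys
}

## uniform points in the dilated footprint of a nucleus, clipped to the field
sample_spots_in_cell <- function(n, poly, margin, w, h) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  lo_x <- max(0, min(poly[, 1]) - margin); hi_x <- min(w - 1e-9, max(poly[, 1]) + margin)
  lo_y <- max(0, min(poly[, 2]) - margin); hi_y <- min(h - 1e-9, max(poly[, 2]) + margin)
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(16L, ceiling((n - length(xs)) * 2.5))
    cx <- stats::runif(m, lo_x, hi_x); cy <- stats::runif(m, lo_y, hi_y)
    ok <- points_in_polygon(cx, cy, poly)
    if (margin > 0) ok <- ok | dist_to_polygon(cx, cy, poly) <= margin
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
  }
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

## case-level context shared by all fields of one case
new_case_ctx <- function(params) {
  ctx <- list()
  for (ch in names(params$channels)) {
    cm <- params$channels[[ch]]
    ctx$homog_state[[ch]] <- if (cm$mode == "unimodal") TRUE else
      stats::runif(1) < cm$on_fraction
  }
  if (params$spatial_pattern == "segregated") {
    k <- params$n_clones
    ctx$clone_seeds <- cbind(stats::runif(k), stats::runif(k))
    for (ch in names(params$channels)) {
      cm <- params$channels[[ch]]
      st <- if (cm$mode == "unimodal") rep(TRUE, k) else
        stats::runif(k) < cm$on_fraction
      # guarantee both patch types when the model is bimodal and k >= 2
      if (cm$mode == "bimodal" && k >= 2L && cm$on_fraction > 0 && cm$on_fraction < 1) {
        if (all(st)) st[sample.int(k, 1)] <- FALSE
        if (!any(st)) st[sample.int(k, 1)] <- TRUE
      }
      ctx$clone_state[[ch]] <- st
    }
  }
  ctx
}

## expression state per cell for one channel under the case's spatial pattern
assign_states <- function(cm, params, ctx, centroids, fov_pos) {
  n <- nrow(centroids)
  if (cm$mode == "unimodal") return(rep(TRUE, n))
  switch(params$spatial_pattern,
    homogeneous = rep(ctx$homog_state_ch, n),
    mixed = stats::runif(n) < cm$on_fraction,
    segregated = {
      ext <- 0.05  # field footprint in virtual tumor-map units
      vx <- fov_pos[1] + (centroids[, 1] / params$width_px - 0.5) * ext
      vy <- fov_pos[2] + (centroids[, 2] / params$height_px - 0.5) * ext
      d2 <- outer(vx, ctx$clone_seeds[, 1], "-")^2 +
        outer(vy, ctx$clone_seeds[, 2], "-")^2
      clone <- max.col(-d2)
      st <- ctx$clone_state_ch[clone]
      attr(st, "clone") <- clone
      st
    },
    gradient = {
      x0 <- params$stroma_fraction * params$width_px
      frac <- (centroids[, 1] - x0) / (params$width_px - x0)
      p <- pmin(1, pmax(0, cm$on_fraction + (frac - 0.5)))
      stats::runif(n) < p
    })
}

#' Simulate one field of view with known ground truth
#'
#' Places non-overlapping convex nuclei in the tumor partition of the field,
#' draws per-cell transcript counts from the channel models, scatters each
#' cell's spots uniformly inside its dilated footprint (planes uniform over
#' the stack) and adds uniform background spots.
#'
#' @param params [sim_params()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the field is fully reproducible.
#' @param field_id,case_id Identifiers stored in the outputs.
#' @param case_ctx Internal case-level context (used by [simulate_case()];
#'   leave `NULL` to draw a fresh one).
#' @param fov_pos Virtual position of the field in the case's tumor map
#'   (used by the `"segregated"` pattern).
#' @return List of class `sim_fov` with elements `meta` ([fov_meta()]),
#'   `outlines` (list of [cell_outline()]), `spots` (a [spot_table()]) and
#'   `truth` (list: per-cell data frame `cells` with true states and counts,
#'   and `spot_cell`, the owning cell id per spot row, `NA` for background).
#' @examples
#' fov <- simulate_fov(sim_params(n_cells_mean = 10, n_cells_sd = 0), seed = 1)
#' nrow(fov$truth$cells)
#' @export
simulate_fov <- function(params, seed = NULL, field_id = "fov1",
                         case_id = "case1", case_ctx = NULL, fov_pos = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(case_ctx)) case_ctx <- new_case_ctx(params)
  if (is.null(fov_pos)) fov_pos <- stats::runif(2)
  meta <- fov_meta(field_id, params$width_px, params$height_px,
                   params$pixel_size_nm, params$n_planes,
                   params$plane_spacing_um, case_id)
  px_um <- meta$pixel_size_um
  n_cells <- min(as.integer(params$n_cells_max),
                 max(1L, as.integer(round(stats::rnorm(1, params$n_cells_mean,
                                                       params$n_cells_sd)))))
  polys <- place_nuclei(n_cells, params)
  centroids <- t(vapply(polys, polygon_centroid, numeric(2)))
  areas_um2 <- vapply(polys, polygon_area, numeric(1)) * px_um^2

  cells <- data.frame(
    cell_id = sprintf("%s_c%03d", field_id, seq_len(n_cells)),
    field_id = field_id, case_id = case_id,
    x_px = centroids[, 1], y_px = centroids[, 2],
    nucleus_area_um2 = areas_um2, clone = NA_integer_,
    stringsAsFactors = FALSE)

  spot_rows <- list()
  owner <- list()
  shared_state <- NULL
  for (ch in names(params$channels)) {
    cm <- params$channels[[ch]]
    ctx_ch <- case_ctx
    ctx_ch$homog_state_ch <- case_ctx$homog_state[[ch]]
    ctx_ch$clone_state_ch <- case_ctx$clone_state[[ch]]
    if (isTRUE(params$correlated_channels) && cm$mode == "bimodal" &&
        !is.null(shared_state)) {
      st <- shared_state
    } else {
      st <- assign_states(cm, params, ctx_ch, centroids, fov_pos)
      if (isTRUE(params$correlated_channels) && cm$mode == "bimodal") {
        shared_state <- st
      }
    }
    if (!is.null(attr(st, "clone"))) cells$clone <- attr(st, "clone")
    mu <- ifelse(st, cm$on_mean_spots, cm$off_mean_spots)
    counts <- as.integer(vapply(mu, function(m) rcounts(1L, m, cm$overdispersion),
                                numeric(1)))
    cells[[paste0("state_", ch)]] <- as.logical(st)
    cells[[paste0("count_", ch)]] <- counts
    for (i in seq_len(n_cells)) {
      if (counts[i] == 0L) next
      xy <- sample_spots_in_cell(counts[i], polys[[i]], params$dilation_margin_px,
                                 params$width_px, params$height_px)
      spot_rows[[length(spot_rows) + 1L]] <- data.frame(
        field_id = field_id, channel = ch, x_px = xy[, 1], y_px = xy[, 2],
        plane = sample.int(params$n_planes, counts[i], replace = TRUE) - 1L,
        stringsAsFactors = FALSE)
      owner[[length(owner) + 1L]] <- rep(cells$cell_id[i], counts[i])
    }
    field_vol <- params$width_px * params$height_px * px_um^2 * meta$depth_um
    n_bg <- stats::rpois(1, params$background_spot_rate * field_vol)
    if (n_bg > 0) {
      spot_rows[[length(spot_rows) + 1L]] <- data.frame(
        field_id = field_id, channel = ch,
        x_px = stats::runif(n_bg, 0, params$width_px - 1e-9),
        y_px = stats::runif(n_bg, 0, params$height_px - 1e-9),
        plane = sample.int(params$n_planes, n_bg, replace = TRUE) - 1L,
        stringsAsFactors = FALSE)
      owner[[length(owner) + 1L]] <- rep(NA_character_, n_bg)
    }
    cells[[paste0("background_", ch)]] <- n_bg
  }
  spots <- if (length(spot_rows)) do.call(rbind, spot_rows) else
    data.frame(field_id = character(0), channel = character(0),
               x_px = numeric(0), y_px = numeric(0), plane = integer(0))
  spots <- spot_table(spots)
  outlines <- lapply(seq_len(n_cells), function(i) {
    # generated nuclei are convex by construction: skip the O(n^2)
    # self-intersection validation of the public constructor
    v <- polys[[i]]
    colnames(v) <- c("x", "y")
    structure(list(cell_id = cells$cell_id[i], field_id = field_id,
                   vertices = v, dilation_margin_px = params$dilation_margin_px),
              class = "cell_outline")
  })
  structure(list(meta = meta, outlines = outlines, spots = spots,
                 truth = list(cells = cells,
                              spot_cell = unlist(owner, use.names = FALSE))),
            class = "sim_fov")
}

#' Simulate one case: independent fields sharing case-level expression
#'
#' The spatial pattern is interpreted at the case level: `"homogeneous"`
#' draws one on/off state for all cells of the case; `"mixed"` draws states
#' i.i.d. per cell; `"segregated"` assigns states by Voronoi clone patches
#' over random seed points in a virtual tumor map, so that whole fields tend
#' to be uniformly "hot" or "cold"; `"gradient"` ramps the on-probability
#' linearly along x within every field.
#'
#' @param params [sim_params()].
#' @param n_fov Number of fields of view.
#' @param seed Optional integer seed for full reproducibility.
#' @param case_id Identifier.
#' @return List of class `sim_case` with `case_id`, `params` and `fovs`
#'   (list of `sim_fov` bundles).
#' @export
simulate_case <- function(params, n_fov = 32L, seed = NULL, case_id = "case1") {
  stopifnot(n_fov >= 1)
  if (!is.null(seed)) set.seed(seed)
  ctx <- new_case_ctx(params)
  fovs <- lapply(seq_len(n_fov), function(k) {
    simulate_fov(params, seed = NULL,
                 field_id = sprintf("%s_f%03d", case_id, k), case_id = case_id,
                 case_ctx = ctx, fov_pos = stats::runif(2))
  })
  structure(list(case_id = case_id, params = params, fovs = fovs, ctx = ctx),
            class = "sim_case")
}

#' Default positive/negative expression models for a two-channel cohort
#'
#' Mean spot counts are set so that, under the default field geometry and the
#' package's default scoring settings (13 x 13 grid with >= 3 dots for HER2,
#' >= 1 dot for ER), group mean pseudo-cell densities land near 0.13 vs 0.04
#' dots/um^3 for HER2 and 0.04 vs 0.02 dots/um^3 for ER.
#'
#' @return Nested list `channels$<gene>$<status>` of [channel_model()]s.
#' @export
cohort_channel_defaults <- function() {
  list(
    HER2 = list(
      positive = channel_model("unimodal", on_mean_spots = 70, overdispersion = 0.25),
      negative = channel_model("unimodal", on_mean_spots = 13, overdispersion = 0.25)),
    ER = list(
      positive = channel_model("unimodal", on_mean_spots = 27, overdispersion = 0.25),
      negative = channel_model("unimodal", on_mean_spots = 11, overdispersion = 0.25)))
}

#' Simulate a cohort of positive and negative cases with reference labels
#'
#' Builds `n_positive + n_negative` cases per channel.  Positivity is
#' assigned per channel (HER2 status for the first `n_positive` cases; ER
#' status over an independent random permutation with the same composition),
#' expression models follow [cohort_channel_defaults()] by default, and
#' clinical-style reference labels (IHC score, DNA FISH amplification, ER%)
#' consistent with the true status are attached for ROC analysis.  A
#' case-level log-normal multiplier (`case_sdlog`) adds between-case score
#' variability within each group.
#'
#' @param n_positive,n_negative Cases per class.
#' @param n_fov Fields of view per case.
#' @param seed Integer seed (mandatory: cohorts are meant to be reproducible).
#' @param channels Nested list as returned by [cohort_channel_defaults()].
#' @param params Base [sim_params()]; per-case channel models are substituted
#'   into it.
#' @param case_sdlog Log-normal sigma of the per-case mean multiplier.
#' @return List of class `sim_cohort` with `cases` (list of `sim_case`),
#'   `records` (case-record data frame with derived positivity and subtype)
#'   and `truth` (per-case true status per channel).
#' @export
simulate_cohort <- function(n_positive = 20L, n_negative = 20L, n_fov = 32L,
                            seed, channels = cohort_channel_defaults(),
                            params = sim_params(), case_sdlog = 0.35) {
  stopifnot(n_positive >= 0, n_negative >= 0, n_positive + n_negative >= 1)
  set.seed(seed)
  n <- n_positive + n_negative
  status <- list()
  status[[names(channels)[1]]] <- rep(c(TRUE, FALSE), c(n_positive, n_negative))
  for (ch in names(channels)[-1]) {
    status[[ch]] <- sample(rep(c(TRUE, FALSE), c(n_positive, n_negative)))
  }
  case_ids <- sprintf("case%02d", seq_len(n))
  cases <- vector("list", n)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    mods <- list()
    for (ch in names(channels)) {
      base <- channels[[ch]][[if (status[[ch]][i]) "positive" else "negative"]]
      mult <- stats::rlnorm(1, -case_sdlog^2 / 2, case_sdlog)
      mods[[ch]] <- channel_model(base$mode, base$on_fraction,
                                  base$on_mean_spots * mult,
                                  base$off_mean_spots * mult,
                                  base$overdispersion)
    }
    p <- params
    p$channels <- mods
    cases[[i]] <- simulate_case(p, n_fov = n_fov, case_id = case_ids[i])
    her2_pos <- if ("HER2" %in% names(channels)) status$HER2[i] else FALSE
    er_pos <- if ("ER" %in% names(channels)) status$ER[i] else FALSE
    rec[[i]] <- data.frame(
      case_id = case_ids[i],
      her2_ihc = if (her2_pos) sample(c("3+", "2+"), 1) else sample(c("0", "1+", "2+"), 1),
      er_percent = if (er_pos) stats::runif(1, 1, 100) else 0,
      pr_percent = stats::runif(1, 0, 100),
      ki67_percent = stats::runif(1, 0, 60),
      stringsAsFactors = FALSE)
    rec[[i]]$her2_amplified <- rec[[i]]$her2_ihc %in% c("3+") ||
      (her2_pos && rec[[i]]$her2_ihc == "2+")
  }
  records <- do.call(rbind, rec)
  records <- derive_subtype(derive_positivity(records))
  truth <- do.call(data.frame, c(list(case_id = case_ids),
                                 stats::setNames(status, paste0("true_", names(status)))))
  if (n_positive > 0 && n_negative > 0) {
    for (ch in names(channels)) {
      lab <- if (ch == "HER2") records$her2_positive else if (ch == "ER")
        records$er_positive else status[[ch]]
      stopifnot(identical(unname(lab), unname(status[[ch]])))
    }
  } else {
    warning("single-class cohort: ROC analysis on it will be undefined")
  }
  structure(list(cases = cases, records = records, truth = truth),
            class = "sim_cohort")
}
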
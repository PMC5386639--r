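test_that("local diversity reproduces hand-computed entropies", {
  g1 <- grid_from_counts(matrix(c(3, 5, 3, 5), 2, 2))
  d1 <- local_diversity(g1, "G", 3)
  expect_equal(d1$L, 2L)
  expect_equal(d1$H, 1)
  expect_equal(d1$H_norm, 1)

  g2 <- grid_from_counts(matrix(c(4, 4, 4, 0), 2, 2))
  d2 <- local_diversity(g2, "G", 3)
  expect_equal(d2$L, 1L)
  expect_equal(d2$H, 0)
  expect_equal(d2$H_norm, 0)   # single level: zero diversity by convention

  g3 <- grid_from_counts(matrix(c(3, 3, 5, 7), 2, 2))
  d3 <- local_diversity(g3, "G", 3)
  expect_equal(d3$L, 3L)
  expect_equal(d3$H, 1.5)
  expect_equal(d3$H_norm, 1.5 / log2(3))

  none <- local_diversity(grid_from_counts(matrix(c(1, 0, 0, 0), 2, 2)), "G", 3)
  expect_true(none$flagged)
})

test_that("entropy matches a brute-force histogram oracle on random grids", {
  set.seed(23)
  for (i in 1:1000) {
    g <- sample(2:6, 1)
    counts <- matrix(rpois(g * g, sample(2:8, 1)), g, g)
    thr <- sample(0:3, 1)
    d <- local_diversity(grid_from_counts(counts, width_px = 512L), "G", thr)
    v <- counts[counts >= thr]
    if (length(v) == 0) {
      expect_true(d$flagged)
      next
    }
    p <- table(v) / length(v)
    expect_equal(d$H, -sum(p * log2(p)))
    expect_equal(d$L, length(p))
    expect_true(d$H_norm >= 0 && d$H_norm <= 1 + 1e-12)
    expect_lte(d$H, log2(max(d$L, 1)) + 1e-12)
    # cross-check against vegan's Shannon index (natural log)
    expect_equal(d$H, vegan::diversity(as.numeric(table(v))) / log(2))
  }
})

test_that("global diversity pools fields and can diverge from local values", {
  gA <- grid_from_counts(matrix(c(4, 4, 4, 4), 2, 2))
  gB <- grid_from_counts(matrix(c(6, 6, 6, 6), 2, 2))
  expect_equal(local_diversity(gA, "G", 3)$H_norm, 0)
  expect_equal(local_diversity(gB, "G", 3)$H_norm, 0)
  glob <- global_diversity(list(gA, gB), "G", 3)
  expect_equal(glob$H_norm, 1)   # pooled p = (1/2, 1/2)

  # identical level distributions: global equals each local
  g1 <- grid_from_counts(matrix(c(3, 5, 3, 5), 2, 2))
  g2 <- grid_from_counts(matrix(c(5, 3, 5, 3), 2, 2))
  expect_equal(global_diversity(list(g1, g2), "G", 3)$H_norm,
               local_diversity(g1, "G", 3)$H_norm)
  expect_equal(global_diversity(list(g1), "G", 3),
               local_diversity(g1, "G", 3))

  # pooling cannot lose levels
  set.seed(4)
  grids <- lapply(1:5, function(i) {
    grid_from_counts(matrix(rpois(16, 5), 4, 4), width_px = 512L)
  })
  gl <- global_diversity(grids, "G", 1)
  expect_gte(gl$L, max(vapply(grids, function(g) local_diversity(g, "G", 1)$L,
                              integer(1))))
})

test_that("diversity dispersion summarizes per-field indices", {
  expect_equal(diversity_dispersion(c(0.8, 0.8, 0.8))$cv, 0)
  d <- diversity_dispersion(c(0.6, 1.0))
  expect_equal(d$mean, 0.8)
  expect_equal(d$cv, sqrt(0.08) / 0.8)
  expect_equal(d$cv, 0.3536, tolerance = 1e-3)
  expect_true(diversity_dispersion(0.7)$flagged)
})

test_that("neighbor differences enumerate unordered adjacent pairs once", {
  g <- grid_from_counts(matrix(c(3, 4, 5, 9), 2, 2))  # rows {3,5; 4,9}
  nd <- neighbor_differences(g, "G", 3)
  expect_equal(sort(nd$diffs), c(1, 1, 2, 4, 5, 6))
  expect_equal(nd$mean, 19 / 6)

  nd4 <- neighbor_differences(g, "G", 4)   # passing cells {5, 4, 9}
  expect_equal(sort(nd4$diffs), c(1, 4, 5))

  uni <- neighbor_differences(grid_from_counts(matrix(7, 3, 3)), "G", 3)
  expect_true(all(uni$diffs == 0))
  expect_equal(uni$n_pairs, 20L)   # 12 rook + 8 diagonal adjacencies

  # brute-force oracle on random grids
  set.seed(9)
  for (i in 1:200) {
    gsz <- sample(2:5, 1)
    m <- matrix(rpois(gsz^2, 4), gsz, gsz)
    thr <- sample(0:3, 1)
    got <- sort(neighbor_differences(grid_from_counts(m, width_px = 512L),
                                     "G", thr)$diffs)
    ref <- numeric(0)
    for (r1 in 1:gsz) for (c1 in 1:gsz) for (r2 in 1:gsz) for (c2 in 1:gsz) {
      if ((r2 > r1 || (r2 == r1 && c2 > c1)) &&
          abs(r1 - r2) <= 1 && abs(c1 - c2) <= 1 &&
          m[r1, c1] >= thr && m[r2, c2] >= thr) {
        ref <- c(ref, abs(m[r1, c1] - m[r2, c2]))
      }
    }
    expect_equal(got, sort(ref))
  }
})

test_that("count shifts leave neighbor differences and level structure alone", {
  set.seed(2)
  m <- matrix(rpois(25, 6) + 3, 5, 5)
  g0 <- grid_from_counts(m, width_px = 512L)
  g7 <- grid_from_counts(m + 7L, width_px = 512L)
  expect_equal(neighbor_differences(g0, "G", 0)$diffs,
               neighbor_differences(g7, "G", 0)$diffs)
  expect_equal(local_diversity(g0, "G", 0)$H, local_diversity(g7, "G", 0)$H)
  expect_equal(local_diversity(g0, "G", 0)$L, local_diversity(g7, "G", 0)$L)
})

test_that("distance-expression scaling handles concordant and degenerate input", {
  cells <- data.frame(cell_id = c("a", "b", "c"), field_id = "f1", channel = "G",
                      count = c(3L, 4L, 5L), density = c(3, 4, 5) / 10,
                      nucleus_area_um2 = 60, footprint_area_um2 = 100,
                      centroid_x_um = c(0, 5, 10), centroid_y_um = 0,
                      dilation_margin_px = 20)
  r <- distance_expression_scaling(cells = cells, channel = "G",
                                   dot_threshold = 3, unit = "cell")
  expect_equal(r$rho, 1)
  expect_equal(r$n_pairs, 3L)

  const <- cells; const$count <- 4L
  rc <- distance_expression_scaling(cells = const, channel = "G",
                                    dot_threshold = 0, unit = "cell")
  expect_true(rc$flagged)

  # pseudo-cell route: three collinear passing pseudo-cells, counts 3, 4, 5
  g <- grid_from_counts(matrix(c(3, 0, 0, 4, 0, 0, 5, 0, 0), 3, 3), width_px = 513L)
  rg <- distance_expression_scaling(grids = list(g), channel = "G",
                                    dot_threshold = 3)
  expect_equal(rg$rho, 1)
})

test_that("inter-regional variability is the CV of per-field mean densities", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:4),
                      field_id = c("f1", "f1", "f2", "f2"), channel = "G",
                      count = 1L, density = c(0.04, 0.06, 0.12, 0.18),
                      nucleus_area_um2 = 60, footprint_area_um2 = 100,
                      centroid_x_um = 1, centroid_y_um = 1,
                      dilation_margin_px = 20)
  v <- interregional_variability(cells, "G", field_ids = c("f1", "f2", "f3"))
  expect_equal(unname(v$field_means), c(0.05, 0.15))
  expect_equal(v$cv, stats::sd(c(0.05, 0.15)) / 0.1)
  expect_equal(v$cv, 0.707, tolerance = 1e-3)
  expect_identical(v$skipped_fields, "f3")

  same <- cells; same$density <- 0.1
  expect_equal(interregional_variability(same, "G")$cv, 0)
})

test_that("co-expression thresholds zero sub-threshold cells before correlating", {
  mk_cells <- function(ch, counts, dens) {
    data.frame(cell_id = sprintf("c%d", seq_along(dens)), field_id = "f1",
               channel = ch, count = counts, density = dens,
               nucleus_area_um2 = 60, footprint_area_um2 = 100,
               centroid_x_um = 1, centroid_y_um = 1, dilation_margin_px = 20)
  }
  d <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  cells <- rbind(mk_cells("A", 5L, d), mk_cells("B", 5L, d))
  expect_equal(coexpression(cells, "A", "B")$rho, 1)

  # a cell below channel B's threshold is zeroed, breaking perfect concordance
  cells2 <- rbind(mk_cells("A", 5L, d), mk_cells("B", c(0L, 5L, 5L, 5L, 5L), d))
  co <- coexpression(cells2, "A", "B", thresholds = c(A = 0, B = 1))
  expect_lt(co$rho, 1)
  expect_equal(co$table$density_b[1], 0)
})

test_that("nucleus-area contrast uses the Mann-Whitney comparison", {
  set.seed(41)
  n <- 40
  cells <- data.frame(cell_id = sprintf("c%d", 1:n), field_id = "f1",
                      channel = "G", count = 1L,
                      density = rep(c(0.01, 0.5), each = n / 2),
                      nucleus_area_um2 = c(rnorm(n / 2, 65, 3), rnorm(n / 2, 72, 3)),
                      footprint_area_um2 = 100, centroid_x_um = 1,
                      centroid_y_um = 1, dilation_margin_px = 20)
  got <- nucleus_area_contrast(cells, "G", density_split = 0.1)
  expect_lt(got$p.value, 0.001)
  expect_gt(mean(got$areas_high), mean(got$areas_low))

  allhi <- nucleus_area_contrast(cells, "G", density_split = 0)
  expect_true(allhi$flagged)
})
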
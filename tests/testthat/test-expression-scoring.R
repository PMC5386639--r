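test_that("grid assignment follows the floor rule and conserves spots", {
  m <- fov_meta("f1", 1024, 1024)
  g <- grid_counts(spots_at(300, 10), m, g = 4)
  expect_equal(g$counts$G[1, 2], 1L)          # floor(300/256) = 1 -> column 2
  expect_equal(sum(g$counts$G), 1L)

  # boundary spot at an exact multiple goes to the higher index;
  # the far edge clamps to the last pseudo-cell
  gb <- grid_counts(spots_at(c(256, 1023.999), c(0, 1023.999)), m, g = 4)
  expect_equal(gb$counts$G[1, 2], 1L)
  expect_equal(gb$counts$G[4, 4], 1L)

  set.seed(42)
  s <- spots_at(runif(100, 0, 1024), runif(100, 0, 1024))
  for (gg in c(1, 9, 13, 16)) {
    expect_equal(sum(grid_counts(s, m, gg)$counts$G), 100L)
  }
  expect_equal(grid_counts(s, m, 1)$counts$G[1, 1], 100L)

  s2 <- s; s2$field_id <- "other"
  expect_error(grid_counts(s2, m, 13), "different field")
})

test_that("pseudo-cell densities follow the prism-volume formula", {
  m <- fov_meta("f1", 1024, 1024, 125, 5, 0.4)
  g <- pseudocell_densities(grid_counts(spots_at(rep(10, 5), rep(10, 5)), m, 13))
  expect_equal(g$cell_area_um2, (1024 / 13 * 0.125)^2)
  expect_equal(g$depth_um, 1.6)
  expect_equal(g$densities$G[1, 1], 0.03224, tolerance = 5e-4)
  expect_equal(sum(g$densities$G > 0), 1L)

  # doubling the plane count (5 -> 9) at equal spacing halves every density
  m9 <- fov_meta("f1", 1024, 1024, 125, 9, 0.4)
  g9 <- pseudocell_densities(grid_counts(spots_at(rep(10, 5), rep(10, 5)), m9, 13))
  expect_equal(g9$densities$G, lapply(g$densities, `/`, 2)$G)

  # independent oracle on random instances: density = count / (area * depth)
  set.seed(7)
  for (i in 1:50) {
    gg <- sample(c(1, 4, 9, 13, 16), 1)
    n <- sample(0:200, 1)
    mm <- fov_meta("f1", sample(c(512, 1024), 1), sample(c(512, 1024), 1),
                   runif(1, 60, 200), sample(2:9, 1), runif(1, 0.2, 1))
    sp <- spots_at(runif(n, 0, mm$width_px - 1e-6), runif(n, 0, mm$height_px - 1e-6))
    gr <- pseudocell_densities(grid_counts(sp, mm, gg))
    area <- (mm$width_px / gg * mm$pixel_size_nm / 1000) *
      (mm$height_px / gg * mm$pixel_size_nm / 1000)
    depth <- (mm$n_planes - 1) * mm$plane_spacing_um
    if (n > 0) expect_equal(gr$densities$G, gr$counts$G / (area * depth))
    expect_equal(sum(gr$counts$G), n)
  }
})

test_that("case scores apply the dot-threshold policy", {
  mk <- function(count) grid_from_counts(matrix(count, 1, 1))
  grids <- lapply(c(0, 0, 4), mk)
  vol <- (1024 * 0.125)^2 * 1.6
  expect_equal(case_score(grids, "G", 3)$score, 4 / vol)
  expect_equal(case_score(grids, "G", 3)$n_passing, 1L)
  expect_equal(case_score(grids, "G", 0, policy = "zero")$score,
               case_score(grids, "G", 0)$score)   # threshold 0: no exclusion
  expect_equal(case_score(grids, "G", 3, policy = "zero")$score, (4 / vol) / 3)

  z0 <- case_score(lapply(c(0, 0), mk), "G", 0)   # all-zero counts, thr 0
  expect_equal(z0$score, 0)
  z <- case_score(lapply(c(0, 0), mk), "G", 3)    # nothing passes: flagged
  expect_equal(z$score, 0)
  expect_true(z$flagged)
  expect_error(case_score(list(), "G", 3), "no fields")
})

test_that("outline dilation matches the Minkowski-sum closed form", {
  sq <- square_outline(side = 10, margin = 0)
  expect_equal(dilate_outline(sq, 0), sq$vertices)

  d20 <- dilate_outline(sq, 20)
  expect_equal(smfishhet:::polygon_area(d20), 100 + 4 * 10 * 20 + pi * 400,
               tolerance = 1e-3)

  areas <- vapply(c(0, 5, 15, 20, 25), function(m) {
    smfishhet:::polygon_area(dilate_outline(sq, m))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))

  # clipping at the field border removes the out-of-field part
  mfull <- fov_meta("f1", 25, 25)
  clipped <- dilate_outline(square_outline(x0 = 0, y0 = 0, side = 10), 20, mfull)
  expect_lt(smfishhet:::polygon_area(clipped),
            smfishhet:::polygon_area(d20))
  expect_true(all(clipped[, 1] >= 0 & clipped[, 1] <= 25))
})

test_that("spots go to the cell with the nearest nucleus boundary", {
  a <- square_outline("cellA", x0 = 0, side = 30, margin = 15)
  b <- square_outline("cellB", x0 = 52, side = 30, margin = 15)
  # (40, 15): inside both dilated footprints, 10 px from A, 12 px from B
  # (15, 15): inside nucleus A only; (45.5, 90): stroma
  s <- spots_at(c(40, 15, 45.5), c(15, 15, 90))
  got <- assign_spots_to_cells(s, list(b, a))
  expect_identical(got$cell_id, c("cellA", "cellA", NA_character_))

  # equidistant overlap spot ties to the lowest cell_id
  s2 <- spots_at(41, 15)
  expect_identical(assign_spots_to_cells(s2, list(b, a))$cell_id, "cellA")
})

test_that("single-cell densities follow the prism formula", {
  m <- fov_meta("f1", 1024, 1024, 125, 5, 0.4)
  sq <- square_outline(x0 = 100, y0 = 100, side = 10, margin = 0)  # 100 px^2
  s <- spots_at(100 + runif(5, 0.5, 9.5), 100 + runif(5, 0.5, 9.5))
  cells <- score_cells(s, list(sq), m)
  expect_equal(cells$count, 5L)
  expect_equal(cells$nucleus_area_um2, 1.5625)
  expect_equal(cells$density, 5 / (1.5625 * 1.6))   # = 2.0 dots/um^3
  expect_equal(cells$density, 2)

  cells0 <- score_cells(spots_at(numeric(0), numeric(0)), list(sq), m,
                        channels = "G")
  expect_equal(cells0$count, 0L)
  expect_equal(cells0$density, 0)

  # same dots in a doubled-area polygon halve the density
  big <- square_outline("c2", x0 = 100, y0 = 100, side = 10 * sqrt(2), margin = 0)
  cb <- score_cells(s, list(big), m)
  expect_equal(cb$density, cells$density / 2, tolerance = 1e-9)
})

test_that("structure-tensor masks behave on flat, scaled and rendered input", {
  m <- fov_meta("f1", 64, 64)
  flat <- matrix(5, 64, 64)
  nm <- nuclei_mask(flat, m, det_threshold = 1e-12)
  expect_false(any(nm$mask))
  expect_true(all(abs(nm$det) < 1e-9))
  expect_error(nuclei_mask(array(0, c(4, 4, 2)), m), "2-D")

  # homogeneity: intensities x c scale the determinant by c^4
  set.seed(3)
  img <- matrix(runif(64 * 64), 64)
  n1 <- nuclei_mask(img, m, det_threshold = 1e-7)
  n2 <- nuclei_mask(img * 10, m, det_threshold = 1e-7 * 1e4)
  expect_equal(n2$det, n1$det * 1e4, tolerance = 1e-8)
  expect_identical(n2$mask, n1$mask)
})

test_that("the mask recovers rendered nuclei from noisy DAPI images", {
  p <- sim_params(width_px = 512L, height_px = 512L, n_cells_mean = 5,
                  n_cells_sd = 0, stroma_fraction = 0.3,
                  channels = list(G = channel_model("unimodal", on_mean_spots = 2)))
  fov <- simulate_fov(p, seed = 31)
  img <- render_image(fov, seed = 32)
  nm <- nuclei_mask(img$dapi, fov$meta)
  truth <- Reduce(`|`, lapply(fov$outlines, function(o) {
    smfishhet:::rasterize_polygon(o$vertices, 512, 512)
  }))
  expect_gt(mean(nm$mask[truth]), 0.9)
  expect_lt(mean(nm$mask[!truth]), 0.1)
})

test_that("mask densities reduce to field densities for trivial masks", {
  m <- fov_meta("f1", 100, 100, 125, 5, 0.4)
  set.seed(11)
  s <- spots_at(runif(60, 0, 49.4), runif(60, 0, 99))  # all in the left half
  full <- matrix(TRUE, 100, 100)
  field_density <- 60 / (100 * 100 * 0.125^2 * 1.6)
  expect_equal(mask_density(s, full, m)$density, field_density)

  half <- matrix(FALSE, 100, 100); half[, 1:50] <- TRUE
  expect_equal(mask_density(s, half, m)$density, 2 * field_density)

  empty <- matrix(FALSE, 100, 100)
  got <- mask_density(s, empty, m)
  expect_true(got$flagged)
  expect_true(is.na(got$density))
})
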
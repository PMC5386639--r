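test_that("simulation is bit-reproducible from its seed", {
  p <- imaging_params()
  a <- simulate_fov(p, seed = 11)
  b <- simulate_fov(p, seed = 11)
  expect_identical(a, b)

  pc <- sim_params(channels = list(G = channel_model("bimodal", 0.4, 20, 2, 0.2)),
                   spatial_pattern = "segregated")
  ca <- simulate_case(pc, n_fov = 3, seed = 5)
  cb <- simulate_case(pc, n_fov = 3, seed = 5)
  expect_identical(ca, cb)

  ra <- render_image(a, seed = 3)
  rb <- render_image(a, seed = 3)
  expect_identical(ra, rb)
})

test_that("truth spot counts plus background reconcile with the spot table", {
  p <- sim_params(channels = list(
    HER2 = channel_model("bimodal", 0.5, 30, 2, 0.3),
    ER = channel_model("unimodal", on_mean_spots = 8, overdispersion = 0.1)))
  for (seed in 1:4) {
    fov <- simulate_fov(p, seed = seed)
    for (ch in c("HER2", "ER")) {
      truth_n <- sum(fov$truth$cells[[paste0("count_", ch)]]) +
        fov$truth$cells[[paste0("background_", ch)]][1]
      expect_identical(truth_n, sum(fov$spots$channel == ch))
    }
    # per-spot ownership is consistent with the table
    expect_length(fov$truth$spot_cell, nrow(fov$spots))
    owned <- table(fov$truth$spot_cell[fov$spots$channel == "HER2"])
    cc <- fov$truth$cells
    for (id in names(owned)) {
      expect_equal(unname(owned[id]), cc$count_HER2[cc$cell_id == id],
                   ignore_attr = TRUE)
    }
  }
})

test_that("nuclei stay inside the field, off the stroma, and never overlap", {
  p <- sim_params(stroma_fraction = 0.25,
                  channels = list(G = channel_model("unimodal", on_mean_spots = 5)))
  for (seed in 1:3) {
    fov <- simulate_fov(p, seed = seed)
    polys <- lapply(fov$outlines, `[[`, "vertices")
    for (v in polys) {
      expect_true(all(v[, 1] >= 0 & v[, 1] <= 1024 & v[, 2] >= 0 & v[, 2] <= 1024))
      expect_true(all(v[, 1] >= 0.25 * 1024 - 1e-9))
    }
    if (length(polys) > 1) {
      for (i in seq_along(polys)[-1]) for (j in seq_len(i - 1)) {
        pi_ <- polys[[i]]; pj <- polys[[j]]
        probe <- rbind(pj, smfishhet:::polygon_centroid(pj))
        expect_false(any(smfishhet:::points_in_polygon(probe[, 1], probe[, 2], pi_)))
      }
    }
  }
})

test_that("degenerate expression models give the expected spot tables", {
  p0 <- sim_params(n_cells_mean = 20, n_cells_sd = 0, background_spot_rate = 0,
                   channels = list(G = channel_model("bimodal", on_fraction = 0,
                                                     on_mean_spots = 30,
                                                     off_mean_spots = 0)))
  fov <- simulate_fov(p0, seed = 2)
  expect_equal(nrow(fov$truth$cells), 20L)
  expect_equal(nrow(fov$spots), 0L)
})

test_that("on-state cells recover the negative-binomial mean (law of large numbers)", {
  p <- sim_params(channels = list(G = channel_model("bimodal", on_fraction = 0.5,
                                                    on_mean_spots = 30,
                                                    off_mean_spots = 1,
                                                    overdispersion = 0.2)))
  set.seed(99)
  cells <- do.call(rbind, lapply(1:53, function(i) simulate_fov(p)$truth$cells))
  expect_gt(nrow(cells), 900)
  on_counts <- cells$count_G[cells$state_G]
  se <- stats::sd(on_counts) / sqrt(length(on_counts))
  expect_lt(abs(mean(on_counts) - 30), 4 * se)
  # on-fraction itself is recovered
  expect_lt(abs(mean(cells$state_G) - 0.5), 4 * sqrt(0.25 / nrow(cells)))
})

test_that("spatial patterns imprint their structure on the truth", {
  pg <- sim_params(channels = list(G = channel_model("bimodal", 0.5, 30, 2, 0.1)),
                   spatial_pattern = "gradient")
  case <- simulate_case(pg, n_fov = 6, seed = 8)
  cells <- do.call(rbind, lapply(case$fovs, function(f) f$truth$cells))
  rc <- rank_correlation(cells$x_px, cells$count_G)
  expect_gt(rc$rho, 0)
  expect_lt(rc$p.value, 0.01)

  ps <- sim_params(channels = list(G = channel_model("bimodal", 0.5, 30, 2, 0.1)),
                   spatial_pattern = "segregated", n_clones = 2L)
  cs <- simulate_case(ps, n_fov = 4, seed = 9)
  clones <- unlist(lapply(cs$fovs, function(f) f$truth$cells$clone))
  expect_true(all(clones %in% 1:2))
})

test_that("cohorts carry consistent labels and separated group densities", {
  coh <- simulate_cohort(n_positive = 3L, n_negative = 3L, n_fov = 4L, seed = 21)
  expect_length(coh$cases, 6L)
  expect_equal(nrow(coh$records), 6L)
  expect_equal(sum(coh$records$her2_positive), 3L)
  expect_equal(sum(coh$records$er_positive), 3L)
  expect_identical(coh$records$her2_positive, coh$truth$true_HER2)

  scores <- vapply(coh$cases, function(case) {
    grids <- lapply(case$fovs, function(f) {
      pseudocell_densities(grid_counts(f$spots, f$meta, 13, channels = "HER2"))
    })
    case_score(grids, "HER2", 3)$score
  }, numeric(1))
  expect_gt(mean(scores[coh$records$her2_positive]),
            mean(scores[!coh$records$her2_positive]))

  expect_warning(simulate_cohort(n_positive = 0L, n_negative = 2L, n_fov = 2L,
                                 seed = 4), "single-class")
})

test_that("infeasible nucleus packing fails loudly", {
  p <- sim_params(width_px = 128L, height_px = 128L, n_cells_mean = 30,
                  n_cells_sd = 0,
                  channels = list(G = channel_model("unimodal", on_mean_spots = 1)))
  expect_error(simulate_fov(p, seed = 1), "infeasible")
})

test_that("image stacks round-trip through multi-page TIFF", {
  set.seed(44)
  a <- array(runif(32 * 24 * 3, 0, 400), c(32, 24, 3))
  p <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(a, p, scale = 1000)
  b <- read_image_stack(p, scale = 1000)
  expect_equal(dim(b), dim(a))
  expect_equal(b, a, tolerance = 1e-6)
})
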
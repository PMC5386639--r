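# Shared fixtures, built in code.

## a square nucleus outline
square_outline <- function(cell_id = "c1", field_id = "f1", x0 = 0, y0 = 0,
                           side = 10, margin = 0) {
  cell_outline(cell_id, field_id,
               cbind(c(x0, x0 + side, x0 + side, x0),
                     c(y0, y0, y0 + side, y0 + side)),
               dilation_margin_px = margin)
}

## spot table from bare coordinates
spots_at <- function(x, y, plane = 0L, field_id = "f1", channel = "G") {
  n <- length(x)
  spot_table(data.frame(field_id = rep_len(field_id, n),
                        channel = rep_len(channel, n),
                        x_px = x, y_px = y, plane = rep_len(plane, n)))
}

## small-field simulation parameters used for imaging fixtures: 256 px
## fields with compact nuclei so that packing stays feasible
imaging_params <- function(on_mean = 12, overdispersion = 0, n_cells = 6) {
  sim_params(width_px = 256L, height_px = 256L, n_cells_mean = n_cells,
             n_cells_sd = 0, nucleus_area_mean_um2 = 25, nucleus_area_sd_um2 = 4,
             channels = list(G = channel_model("unimodal", on_mean_spots = on_mean,
                                               overdispersion = overdispersion)),
             dilation_margin_px = 10)
}

## pseudo-cell grid built directly from a count matrix (counts placed at the
## pseudo-cell centers of a synthetic field)
grid_from_counts <- function(m, channel = "G", width_px = 1024L) {
  g <- nrow(m)
  meta <- fov_meta("f1", width_px, width_px)
  side <- width_px / g
  idx <- which(m > 0, arr.ind = TRUE)
  xs <- (idx[, "col"] - 0.5) * side
  ys <- (idx[, "row"] - 0.5) * side
  reps <- m[idx]
  spots <- spots_at(rep(xs, reps), rep(ys, reps), channel = channel)
  grid_counts(spots, meta, g, channels = channel)
}
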
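# smfishhet

Quantitative scoring and spatial heterogeneity analysis for single-molecule
RNA FISH (smFISH) in archival (FFPE) tissue sections, built around HER2/ER
profiling in breast cancer.

In smFISH every mature transcript of a targeted gene appears as one
diffraction-limited fluorescent spot, so a field of view yields absolute
per-molecule coordinates. `smfishhet` turns those spot tables into
clinically interpretable numbers and validates every step on synthetic
cohorts with known ground truth:

* **Pseudo-cell scoring** — each 1024 × 1024 px field (125 nm/px, 5 focal
  planes 0.4 µm apart) is split into a regular g × g grid of "pseudo-cells";
  the per-pseudo-cell density is
  `count / ((n_planes − 1) · Δz · area)` (dots/µm³) and a case's *smFISH
  score* is the mean density over all its thresholded pseudo-cells
  (defaults: g = 13, ≥ 3 dots for HER2, ≥ 1 dot for ER).
* **Segmented-cell scoring** — DAPI nucleus polygons dilated by a uniform
  margin (default 20 px) define approximate cells; spots are assigned to
  the nearest containing footprint and densities use the prism over the
  clipped footprint.
* **Structure-tensor region masks** — nuclei-containing regions from the
  z-projected DAPI image (σ_gradient = 250 nm, σ_tensor = 875 nm, common
  determinant threshold) and the spot density inside them.
* **Diagnostic calibration** — ROC over a fixed grid of 200 cutoffs
  (0.001–0.2 dots/µm³), trapezoidal AUC (plus a curve-minus-diagonal mode),
  best operating point, and grid/threshold/margin parameter sweeps against
  IHC + DNA FISH reference labels; St. Gallen-style surrogate subtyping.
* **Intra-tumor topography** — local and global normalized Shannon
  diversity of pseudo-cell expression levels, neighbor count differences,
  distance–expression scaling, inter-regional CV, two-channel single-cell
  co-expression, nucleus-area contrasts.
* **Spot calling** — scale-normalized Laplacian-of-Gaussian detection with
  non-maximum suppression, z-merging and sub-pixel localization.
* **Registration** — normalized cross-correlation placement of
  high-magnification fields onto whole-section scans (A1: scale +
  translation) chained with a least-squares reference-point affine (A2);
  spots map as D′ = A2 A1 D.
* **Synthetic cohorts** — a ground-truthed generator (cells, clone
  patterns, negative-binomial expression, rendered image stacks) matching
  the statistical structure the analysis assumes.

## Worked example

```r
library(smfishhet)

cohort <- simulate_cohort(n_positive = 10, n_negative = 10, n_fov = 16,
                          seed = 7)
scores <- vapply(cohort$cases, function(case) {
  grids <- lapply(case$fovs, function(f) {
    pseudocell_densities(grid_counts(f$spots, f$meta, g = 13,
                                     channels = "HER2"))
  })
  case_score(grids, "HER2", dot_threshold = 3)$score
}, numeric(1))

round(range(scores), 3)
#> [1] 0.028 0.278

roc <- roc_curve(scores, cohort$records$her2_positive)
roc_auc(roc)
#> [1] 1
best_operating_point(roc)
#> $t
#> [1] 0.05
#> $sensitivity
#> [1] 1
#> $specificity
#> [1] 1
#> $distance
#> [1] 0
```

Twenty simulated cases whose positive group was generated around
0.13 dots/µm³ and negative group around 0.04 dots/µm³ are perfectly
separated by the pseudo-cell smFISH score: the ROC curve reaches the
(0, 1) corner, and a cutoff of 0.05 dots/µm³ classifies every case
correctly.

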
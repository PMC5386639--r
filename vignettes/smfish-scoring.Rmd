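---
title: "Transcript-density scoring and spatial heterogeneity analysis for smFISH in tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript-density scoring and spatial heterogeneity analysis for smFISH in tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfishhet)
```

## The problem

Single-molecule RNA FISH (smFISH) renders every mature transcript of a
targeted gene as one diffraction-limited fluorescent spot. In archival
(FFPE) tumor sections this gives absolute per-cell transcript counts for
clinically important biomarkers — here HER2 and the estrogen receptor (ER)
in breast cancer — together with the position of every molecule in the
tissue. Two analysis questions follow:

1. **Diagnostic scoring.** Can a density summary of the spots classify a
   tumor as HER2- or ER-positive as reliably as immunohistochemistry (IHC)
   plus DNA FISH, without manual cell segmentation?
2. **Intra-tumor topography.** How variable is expression between cells and
   between regions of the same tumor, and is that variability spatially
   organized?

`smfishhet` implements the full quantitative chain for both questions, plus
a synthetic-cohort generator with known ground truth so that every step can
be validated end to end.

## Pseudo-cells and the smFISH score

A field of view (FOV) is a `width_px` × `height_px` image stack of
`n_planes` focal planes spaced `plane_spacing_um` apart (defaults: 1024 ×
1024 px at 125 nm/px, 5 planes, 0.4 µm). Instead of segmenting cells, the
field is split into a regular g × g grid of square *pseudo-cells* with exact
fractional-pixel boundaries (side `width_px / g`). For each pseudo-cell the
transcript density is

$$\rho = \frac{\text{spot count}}{(n_\text{planes}-1)\,\Delta z \; A},$$

with $A$ the pseudo-cell area in µm² and $(n_\text{planes}-1)\Delta z$ the
imaging depth: the tissue is only sampled between the first and last plane,
so the prism height uses one fewer than the plane count. The **smFISH
score** of a case is the mean density over all its pseudo-cells, pooled
across FOVs, after a dot threshold that suppresses background (counts below
the threshold are *excluded* from the mean; `policy = "zero"` keeps them at
density zero instead — both policies are available because either reading
is defensible, and the exclusion reading matches how the thresholds are
used in the diversity analysis).

The package's default settings are a 13 × 13 grid with thresholds of 3 dots
(HER2) and 1 dot (ER) per pseudo-cell; those combinations maximize
diagnostic performance over the conventional sweep (grids 9–16, thresholds
0–3, `parameter_sweep()`).

The segmented-cell route (`score_cells()`) uses DAPI nucleus polygons
dilated by a uniform margin (default 20 px = 2.5 µm, round-join Euclidean
buffer) to capture cytoplasmic transcripts. A spot belongs to the cell
whose dilated footprint contains it; in overlaps it goes to the nearest
undilated nucleus boundary (ties to the smallest cell id). The density
prism uses the dilated footprint clipped at the field borders, since that
is the region spots are counted in; `area = "nucleus"` switches to the
undilated base for sensitivity analyses.

A third, segmentation-free route (`nuclei_mask()`) finds nuclei-containing
regions from the z-projected DAPI image with a gradient structure tensor
(σ_gradient = 250 nm, σ_tensor = 875 nm; 2 px and 7 px at 125 nm/px) and a
common determinant threshold, then computes the spot density inside the
mask (`mask_density()`). The determinant scales with the fourth power of
image intensity, so the automatic threshold applies Otsu's method to its
fourth root; in a real study the threshold is chosen once and reused for
all images.

## Diagnostic calibration

`roc_curve()` sweeps the fixed grid of 200 cutoffs t = 0.001 … 0.200
dots/µm³; a case is called positive when its score ≥ t, and TP/FP/TN/FN,
sensitivity and specificity follow the standard clinical definitions
against the reference labels (IHC 3+ or IHC 2+ with DNA FISH amplification
for HER2; ER ≥ 1% for ER — `derive_positivity()`). Scores above 0.2 are
positive at every cutoff; the cap is far above both group means, so in
practice no information is lost.

Two AUC conventions are provided. The default `"conventional"` mode is the
trapezoidal area under the (1 − specificity, sensitivity) polyline with
(0,0) and (1,1) appended — the 0–1 scale on which reported AUC values above
0.9 live, with 0.5 meaning chance. The `"curve-minus-diagonal"` mode
subtracts 0.5 and reports the area between the curve and the chance
diagonal (maximum 0.5); it is retained because the quantity is sometimes
described that way even when values are printed on the conventional scale.
`best_operating_point()` returns the cutoff closest to the perfect corner
(0, 1), ties to the smallest cutoff.

Group comparisons use the two-tailed Mann–Whitney test: exact P by complete
enumeration of group assignments for combined n ≤ 12 (valid under ties),
tie-corrected normal approximation otherwise. Correlations are Spearman's ρ
on mid-ranks with the two-tailed t-distribution P value
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; zero-variance input is flagged rather
than guessed.

## Diversity and topography

For one FOV, the *expression levels* are the distinct integer dot counts
among pseudo-cells passing the channel's threshold. With $p_l$ the fraction
of passing pseudo-cells at level $l$, the Shannon index is
$H = -\sum_l p_l \log_2 p_l$, normalized to $\bar H = H / \log_2 L$
(defined as 0 when only one level is present — a single level is zero
diversity). The *global* index applies the same computation to pseudo-cells
pooled over all FOVs of a case. Levels are raw integer counts rather than
binned densities because the index is only well defined on a discrete
support; a consequence worth knowing is that with large counts almost all
levels are distinct and $\bar H$ saturates near 1, so contrasts between
cases are carried mostly by low-count fields and by the dispersion of the
per-field indices (`diversity_dispersion()`: mean and CV across FOVs).

`neighbor_differences()` collects |count difference| over unordered pairs
of 8-neighborhood-adjacent passing pseudo-cells (each pair counted once;
border pseudo-cells contribute only existing neighbors).
`distance_expression_scaling()` correlates, within fields, all pairwise
Euclidean separations (µm, pseudo-cell centers or cell centroids) with
absolute expression differences, concatenated per case. Count differences
are the default; for pseudo-cells of equal volume the rank correlation is
identical with densities. Distances are reported in µm, though ρ does not
depend on the unit.

Per-cell statistics complete the picture: `interregional_variability()`
(CV across FOVs of the per-FOV mean single-cell density),
`coexpression()` (per-cell two-channel density correlation with counts
below the per-channel cell thresholds — 0 dots HER2, 1 dot ER — zeroed),
and `nucleus_area_contrast()` (Mann–Whitney comparison of nucleus areas
between high- and low-expressing cells).

## Spot calling and registration

`detect_spots()` is a scale-normalized Laplacian-of-Gaussian caller:
per-plane band-pass at σ = 1.3 px (a diffraction-limited PSF at 125 nm/px),
local maxima above threshold, greedy brightest-first suppression within
`min_separation_px`, optional merging of maxima on adjacent planes
(`z_merge`, on by default so each molecule counts once per stack — the
densities divide by the full stack depth), and sub-pixel localization by a
quadratic fit of the 3 × 3 response neighborhood. The automatic threshold
is the knee of the response histogram, floored at median + 8 MAD so it can
never land inside the background-fluctuation tail; it is deliberately
overridable because any fixed policy is a choice, not a property of the
data.

`register_highmag()` maps a high-magnification field onto a stitched scan:
the field is rescaled to the scan's pixel size by exact area-weighted
resampling, placed by normalized cross-correlation over all valid
positions (zero-mean template, per-window scan statistics from integral
images), and the result is the affine A1 = translation ∘ scaling — no
rotation, which is deferred to the reference-point transform A2
(`fit_affine()`, least squares, ≥ 3 non-collinear pairs, residual RMS
reported). Spots map through the chain as D′ = A2 A1 D (`map_spots()`).
Placement is at integer scan pixels; sub-pixel refinement is not applied
because the downstream overlay tolerance is one scan pixel.

## The synthetic cohort generator

`simulate_fov()` / `simulate_case()` / `simulate_cohort()` generate data
matching the statistical structure the analysis assumes, with full ground
truth:

* **Geometry.** 1024 × 1024 px fields at 125 nm/px, 5 planes at 0.4 µm;
  19 ± 10 cells per field (truncated to [1, 40]: the upper cap keeps
  dart-throwing placement of ~65 µm² nuclei feasible and covers > 98% of
  the distribution); nuclei are ellipse-perturbed convex polygons of
  8–14 vertices with areas ~N(65, 15²) µm², placed by dart throwing with
  disjoint bounding circles, entirely inside the field and outside a
  stromal margin (default 20% of the field width) that stays cell-free.
* **Expression.** Per-cell counts are negative-binomial with mean set by
  the cell's on/off state and overdispersion φ (Var = µ + φµ²; φ = 0 is
  Poisson). Bimodal channels draw the state per cell; `correlated_channels`
  shares one state draw across channels to engineer a co-expressing
  subpopulation.
* **Spatial patterns.** `homogeneous` draws one state for the whole case;
  `mixed` draws i.i.d. states; `segregated` assigns states by Voronoi clone
  patches in a virtual tumor map so whole fields tend to be uniformly hot
  or cold; `gradient` ramps the on-probability linearly along x within each
  field.
* **Spots.** Uniform inside the cell's dilated footprint (planes uniform),
  plus uniform background at 0.001 dots/µm³ — enough to exercise the dot
  thresholds without dominating any score.
* **Cohorts.** `cohort_channel_defaults()` sets per-cell means (HER2 70/13,
  ER 27/11 spots per cell for positive/negative cases) chosen by forward
  simulation so that group mean pseudo-cell scores land near 0.13 vs 0.04
  dots/µm³ for HER2 and 0.04 vs 0.02 for ER under the default scoring
  settings — the density regimes the method is designed to distinguish. A
  per-case log-normal multiplier (σ = 0.35) creates realistic between-case
  spread within groups. Reference labels (IHC score, amplification, ER%)
  are generated consistently with each case's true status.

`render_image()` turns a field into images: spots as isotropic 2-D
Gaussians (σ = 1.3 px) on their own plane — the integrated signal above
background is amplitude × 2πσ² — and a DAPI channel from filled nucleus
polygons with smooth chromatin-like texture, under Poisson shot noise plus
Gaussian read noise. Everything is bit-reproducible from a single seed.

### What the generator does and does not emulate

It reproduces the density regimes, count overdispersion, on/off population
structure, clone geometry, stromal gaps and optical blur that the scoring
and topography statistics rely on. It does **not** emulate FFPE
autofluorescence texture, nucleus shape irregularity beyond convex
perturbation, 3-D nucleus extent, segmentation error, or optical crosstalk
between channels. Tests passing on synthetic cohorts therefore validate
the *computational chain* — formulas, thresholds, conservation, ordering of
group differences — not the wet-lab robustness of the assay.

## Validation scenarios and problem sizes

The test-suite cohort uses 20 positive + 20 negative cases with 32 FOVs
each (the lower end of the 32–79 FOVs-per-case regime), which keeps the
suite's end-to-end blocks at a few minutes on one CPU while leaving the
group-separation and permutation analyses well powered.

Two validation scenarios deviate from the cohort defaults, deliberately:

* **Diversity contrast.** Cases compared for local-diversity dispersion use
  a per-field cell-count spread of ±4 instead of ±10: near-empty fields
  produce degenerate single-level indices whose noise would otherwise
  dominate the CV regardless of the spatial pattern. The homogeneous
  comparator is a uniformly expressing case (on fraction 1), the cleanest
  realization of "one state for all cells". The global-vs-local divergence
  is summarized as the ratio of the global level count L to the mean local
  L — pooling can only add levels, and the gain is largest when fields
  differ — because the normalized-entropy difference barely orders the
  patterns once counts are large enough that levels rarely collide.
* **Distance–expression scaling.** Gradient detection uses denser fields
  (35 cells of ~40 µm²), a strong on/off contrast (60 vs 5 spots, φ = 0.05),
  a 9 × 9 grid and threshold 1. With the default sparse fields, pseudo-cell
  counts are dominated by how much cell area a square happens to cover, and
  that coverage noise (plus threshold censoring of the low-expression tail)
  buries the gradient signal at the pair level. The denser scenario lets
  each pseudo-cell average several cells, which is the regime in which the
  statistic is informative; `mixed` control cases stay within |ρ| < 0.05.

## Numerical choices and degenerate inputs

* Pseudo-cell boundaries are exact fractions of the field width, so all g²
  squares share one area term; boundary spots go to the higher index and
  the far edge clamps.
* Polygon dilation discretizes corner arcs at ≤ 2° steps (area error well
  under 0.1%); the offset construction is exact for convex polygons and
  accurate for mildly concave outlines while the margin is small relative
  to the local feature size, which holds for nucleus outlines.
* `H̄ := 0` when L = 1; no passing pseudo-cells, empty masks, zero-variance
  correlations, single-class label sets and empty strata are *flagged*,
  never silently converted to numbers.
* NCC windows with near-zero variance get correlation 0; peak confidence
  below 0.5 sets a flag instead of failing.
* All randomness flows through explicit integer seeds; identical seeds give
  bit-identical spot tables, truth records and rendered stacks.

## Known limitations

* The structure-tensor mask is region-level by design; it does not split
  touching nuclei and is not a per-cell segmentation.
* The Shannon index on raw counts saturates for highly expressed genes;
  comparisons should then rely on the dispersion and neighbor statistics.
* A1 carries no rotation; fields acquired with appreciable rotation
  relative to the scan would need the residual absorbed by A2.
* The Mann–Whitney exact branch enumerates up to C(12, 6) = 924
  assignments; beyond combined n = 12 the normal approximation is used
  without a continuity correction.

## A worked example

```{r example, eval = FALSE}
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

roc <- roc_curve(scores, cohort$records$her2_positive)
roc_auc(roc)
best_operating_point(roc)
```
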
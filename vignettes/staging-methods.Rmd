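---
title: "Staging chondrocyte dedifferentiation from visual indicators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging chondrocyte dedifferentiation from visual indicators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondrostage)
```

## The biological model

Chondrocytes expanded in monolayer lose their hyaline-cartilage
phenotype in two phases. Early-stage cells (around passage 2) remain
plastic — they transiently upregulate antioxidative markers, RBP4 and
SOD3 peaking mid-culture — and can still recover matrix-forming
capacity in 3D culture. Late-stage cells accumulate structural damage:
IFITM3 and filamentous actin rise monotonically, cells flatten into
fibroblast-like shapes, and both cell and nucleus enlarge. The package
operationalizes this biphasic model as a six-indicator panel (four
immunostained marker intensities plus cell and nucleus size) measured
on 20 randomly selected cells per sample, and stages unknown samples
against a P0/P2/P4/P8 reference.

## The staging procedure

1. **Quantification.** Nuclei are segmented from DAPI, cell footprints
   from phalloidin seeded at the nuclei, and per cell the mean gray
   value of each marker channel plus the two areas are measured
   (`quantify_image()`). 20 cells are selected uniformly without
   replacement with a mandatory seed (`select_cells()`).
2. **Matrix capture.** Profiles are assembled into a rounds ×
   (sample, indicator) matrix and normalized per indicator to integers
   in [0, 14 000] by a linear min–max map, rounded half-up
   (`normalize_matrix()`). Normalization is fitted per indicator across
   all samples jointly: this keeps indicators on a common scale while
   preserving between-sample contrasts; a global-scope alternative is
   available via the `scope` argument. A constant indicator maps to 0
   with a warning. The fitted (min, max) are frozen on the reference so
   queries are projected into the *same* coordinate system; query
   values outside the fitted range are clipped, not extrapolated,
   because the reference range defines the model's domain.
3. **Round sorting.** Within every (sample, indicator) column the 20
   values are sorted ascending (`sort_rounds()`). Rounds are
   exchangeable — each is an independently chosen cell, not a matched
   observation across indicators — so sorting loses nothing and makes
   all downstream distances *exactly* invariant to measurement order.
   The robustness-to-reordering property is thereby a hard invariant
   rather than an empirical observation.
4. **Distance and assignment.** Each sample is its concatenated
   120-vector (6 indicators × 20 sorted rounds). Distances are plain
   Euclidean; the intensity matrix is not count data, so
   count-model variance-stabilizing transforms are undefined for it and
   an optional `log1p` flag stands in where variance stabilization is
   wanted. The query takes the stage of its nearest reference. Ties go
   to the earlier stage (the conservative call for a therapy-suitability
   screen) and are flagged ambiguous.
5. **Confidence and out-of-model.** Confidence is
   `d_other / (d_other + d_assigned)` over the two nearest *stages* — a
   ratio in (0.5, 1] for unambiguous calls, with no probabilistic
   calibration because no calibration data exist. A query whose nearest
   distance exceeds 1.5× the median reference-to-reference distance is
   flagged `out_of_model` ("not close to any group") rather than
   trusted as a firm call; 1.5 is configurable.
6. **Batches.** Separate staining batches share one anchor sample
   (the Model-P2 healthy control). `harmonize_batches()` fits, per
   batch and indicator, the affine map sending the batch anchor's
   (median, IQR) onto the first batch's, which is exact whenever
   batches differ by a positive-gain affine distortion. Robust
   location/scale anchoring is used because only a single shared sample
   exists per batch — quantile normalization has nothing to train on.

PCA (`pca_embed()`) is column-centered with components sign-fixed so the
largest-magnitude loading is positive; queries are projected with the
reference-fitted rotation.

## Synthetic-data generator

The generator is first-class code: it defines the study conditions under
which every claim about the pipeline is tested.

* **Stage parameters** (`make_stage_params()`) default to the packaged
  YAML config, which is labelled *illustrative, not measured*: the
  literature gives ordinal relations (RBP4/SOD3 maximal at P2;
  IFITM3/F-actin and sizes strictly increasing P0→P8), not calibrated
  intensities. Defaults encode those relations with marker CVs of 0.25
  — a realistic spread for per-cell immunofluorescence — cell diameters
  growing 18→34 µm and nuclei 9→16 µm across passages, and a
  cell–nucleus size correlation of 0.6.
* **Intensities** are log-normal (positive, right-skewed, the standard
  fluorescence noise shape), parameterized by arithmetic mean and CV.
  **Sizes** are correlated truncated normals restricted to
  0 < nucleus < cell; areas are ellipse areas computed from the sampled
  equivalent diameters, so area is independent of rendering aspect
  ratio. Aspect ratios rise with stage (1.0–1.4 at P0 up to 1.0–2.2 at
  P8) to mimic the round→fibroblast-like transition.
* **Images** (`render_image()`) place non-overlapping ellipse pairs on
  a 1024 × 1024 px canvas at 0.5 µm/px, fill marker channels uniformly
  per cell, and add Poisson shot noise plus Gaussian read noise
  (σ = 5 by default); Gaussian PSF blur is off by default and available
  behind a flag. Pixel values stay continuous in memory and are
  quantized to 16-bit only when written as TIFF — this keeps the
  zero-noise render ↔ re-measurement loop exact to machine precision.
  Each stained marker is drawn from an independent cell set by default
  (separate coverslips); `shared_cells = TRUE` models co-staining.
* **Trajectories** (`simulate_trajectory_matrix()`) draw pseudotime
  uniformly on [0, 1] and build genes from five archetypes — step-down
  at t = 0.15, linear down, step-up at t = 0.85, linear up, one full
  sine period (the minimal non-monotone archetype, two internal
  extrema) — plus flat background, each as
  `baseline + amplitude·template + N(0, noise_sd)` truncated at zero.

What the generator does **not** emulate: uneven illumination, focus
drift, cell debris and clumping in images; library-size variation,
dropout and overdispersion in expression. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
structure, not robustness to every artifact of real microscopy or
scRNA-seq.

## Segmentation design

Nuclei: Otsu threshold, hole filling, distance-transform watershed
(tolerance 1 px) to split touching nuclei, minimum-area filter
(10 µm²). Cells: thresholded phalloidin foreground partitioned by
propagation from the nucleus seeds, so each cell inherits its nucleus
label and seedless debris is dropped. Cells touching the border are
excluded by default (their areas would be truncated).

Two choices matter numerically:

* **Threshold domain.** The default method is `"otsu_log"`: Otsu
  computed on `log1p` intensities. On sparse images whose cells span a
  wide brightness range (per-cell phalloidin means of 30–160 over a
  dark background), linear Otsu can maximize between-class variance by
  splitting *dim cells from bright cells* instead of background from
  foreground, silently truncating the dimmest cell to its nucleus. In
  log domain the background/foreground gap dominates and the split is
  correct. Linear `"otsu"` and `"fixed"` remain available.
* **Threshold histogram vs threshold application.** The threshold is
  derived from a σ = 2 px Gaussian-smoothed copy of the channel — so
  read noise cannot percolate the background above threshold and flood
  the seeded propagation — but applied to the raw pixels, so object
  boundaries are not dilated by the blur. With default noise this keeps
  measured areas within ~2% of ground truth; at zero noise the masks
  are exact.

## Pattern classification design

Each gene's `log1p` trajectory is averaged in 10 equal-width pseudotime
bins (empty bins interpolated), then:

* the **flat test** and **extrema count** use a 3-bin moving-average
  smooth of the bin means (noise suppression); a gene whose smoothed
  range is below 10% of its value range is FLAT — background genes are
  never forced into one of the five biological classes;
* the **net change** Δ and **midpoint-crossing time** t½ use the
  *unsmoothed* bin means: edge smoothing biases an exactly linear
  gene's crossing away from 0.5, and the linear-gene-crosses-at-½
  property is part of the rule's definition;
* an internal turning point equal to the profile's global maximum or
  minimum is never pruned by the prominence filter (threshold 0.15 on
  the [0, 1]-scaled bins): after binning, smoothing and log transform,
  the sine archetype's leading rise can compress below any fixed
  prominence threshold, yet a global extremum away from the boundary is
  structural by definition.

Decision rule: FLAT if range ratio < 0.1; else TIDE_WAVE if ≥ 2
prominent internal extrema or |Δ| < 0.2 (large range without net change
is non-monotone); else decreasing genes are IMMEDIATE_DOWN when
t½ ≤ 0.3 and GRADUAL_DOWN otherwise; increasing genes are DELAYED_UP
when t½ ≥ 0.7 and GRADUAL_UP otherwise. All thresholds live in
`qc_config()`. The rule is invariant to positive affine transforms of
the expression values.

Dynamic genes are ranked by a likelihood-ratio test of a natural-spline
(df = 3) mean model against a constant mean, Gaussian on `log1p`
values, BH-adjusted, q < 0.01, top 1 000 — a transparent approximation
of the trajectory-tooling test whose exact statistic is not specified
anywhere reproducible.

QC order is fixed as cells → genes → total-count window; order changes
results (a cell can sit exactly at the min-genes threshold thanks to a
gene the gene filter removes), so the order is part of the contract and
regression-tested. Sd uses the n−1 denominator; boundary cells exactly
at mean ± 2 sd are retained.

## Problem sizes and determinism

The shipped studies use 20 rounds × 6 indicators per sample, 4
reference samples, 40 queries (10 per stage); trajectory studies use
300 cells with 10 genes per archetype class, 50–950 flat genes and
noise sd 0.2; image studies render 20–24 cells per 1024² canvas. These
sizes match the measurement effort the staging protocol itself
prescribes (20 cells per marker per sample) while keeping a full
simulation-to-report cycle interactive. Every stochastic step takes an
explicit seed; pipeline runs derive per-module substreams from one root
seed and embed the full configuration in their reports, making two runs
with the same config byte-identical.

## Known limitations

* The nearest-reference rule formalizes what was originally a visual
  PCA-proximity judgement; with one reference sample per stage the
  confidence ratio reflects geometry, not a calibrated error rate.
* Late-stage heterogeneity is real: samples far from all references are
  flagged `out_of_model` rather than staged, mirroring the observation
  that the panel identifies good-quality (early) cells more sharply
  than it discriminates among degraded ones.
* Segmentation assumes isolated-to-moderately-touching cells; heavily
  confluent cultures would need a different cell-body prior.
* The min–max normalization is sensitive to single extreme reference
  values by construction; the 20-round sorted representation dampens
  but does not remove this.
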
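---
title: "Radiomics survival signatures: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics survival signatures: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiosurv)
```

# The problem and the model

`radiosurv` stratifies glioblastoma patients into short- (< 10 months),
medium- (10–15 months) and long-term (> 15 months) survivor groups from
pre-operative multi-parametric MRI. The pipeline has four statistical
stages, each exposed as its own function family and assembled by
`radiomics_signature()`:

1. **Standardization.** Each channel is rescaled by the μ ± 3σ rule:
   with μ the mean and σ the population standard deviation of the grey
   levels over the brain support, intensities are clipped to
   [μ − 3σ, μ + 3σ] and mapped affinely onto the 8-bit range [0, 255].
   The transform is exactly invariant under positive affine intensity
   changes (`a·V + b`, `a > 0`), which is the point: scanner gain and
   offset drop out. The cost — also by design of the rule — is that
   relative differences between grey levels are not preserved.
2. **Feature extraction.** A fixed catalogue of 147 features per patient
   (see below).
3. **Selection.** A median-absolute-deviation filter removes features
   that are constant for at least half the cohort (MAD = 0), then an
   L1-penalized linear model of survival time on the standardized
   features is fit over a 100-point penalty grid; the penalty minimizing
   10-fold cross-validated deviance defines the kept subset.
4. **The signature.** An *unpenalized* Cox proportional-hazards fit on
   the kept features yields log-hazard coefficients βᵢ with Wald
   p-values; each patient's risk score is the linear form Σᵢ βᵢ·xᵢ.
   Two fixed cutoffs stratify scores into low/medium/high risk, mapped
   to predicted long/medium/short survival.

The cutoffs follow the half-median rule: on the discovery cohort the
median score of the short-survivor group is halved to give the high
cutoff, and the median of the long-survivor group is halved to give the
low cutoff. Halving approximates the 25th percentile of each tail group
and pulls the thresholds into the overlap region between groups. Scores
exactly equal to a cutoff fall to the medium class (strict inequalities
define the outer classes). Once derived, the cutoffs are frozen and
applied unchanged to validation data — they are part of the model, not
re-estimated.

Assumptions worth stating: survival is treated as fully observed (no
censoring) unless an event indicator is supplied; the Cox stage assumes
proportional hazards in the selected features; and the Gaussian LASSO
stage treats survival time, not its log, as the working outcome for
selection only — coefficients used in the score never come from the
penalized fit.

# The 147-feature catalogue

Features are computed per (region, modality) pairing — whole tumor (WT)
on T2-FLAIR, active tumor (AT) on T1-Gd, tumor core (TC) on T2 — 48 per
pairing, plus 3 joint ratios:

| block | count | contents |
|---|---|---|
| shape | 14 | tumor/brain volumes (mm³) and their ratio; convex, filled, mask and brain slice areas (mm²); area ratio; eccentricity; orientation; equivalent diameter; solidity; extent; perimeter |
| intensity | 14 | min, max, median, mean, range, variance, 2nd/3rd central moments, 256-bin entropy (bits), kurtosis, RMS, skewness, SD, mean absolute deviation |
| GLCM | 14 | contrast, correlation, energy, homogeneity, sum variance, sum average, variance, autocorrelation, entropy; sum entropy, difference entropy, sum variance, difference variance on the two-offset matrix; range of the other 13 |
| HOG | 3 | sum, median, SD of the oriented-gradient descriptor |
| LBP | 3 | sum, mean, SD of the uniform-pattern histogram |

Names follow `Modality_Region_FeatureName_F<index>` with blocks ordered
WT (1–48), AT (49–96), TC (97–144) and the joint ratios last (145–147),
so e.g. feature 139 is `T2_TC_SumHOG_F139`. `feature_manifest()` returns
the full order; `write_feature_manifest()` serializes it as JSON.

Two catalogue names disambiguate a collision: the catalogue contains
both a first-order and a co-occurrence entropy/variance per block, so
the GLCM versions are prefixed (`GLCMEntropy`, `GLCMVariance`). Note
also that *MAD* appears in two senses in this field — the mean absolute
deviation intensity feature and the median absolute deviation filter —
and the two are named apart in code (`MeanAbsoluteDeviation` vs
`mad_filter()`).

## 2-D versus 3-D

Volumes are 3-D (voxel counts × voxel volume). Everything else is
computed on one axial slice per region: the slice with the largest
in-slice mask area (ties to the lowest index), cropped to the mask's
tight bounding box. Intensity statistics use the masked pixels of that
normalized slice. This allocation is the only one consistent with a
catalogue that lists areas, perimeter and 2-D ellipse descriptors
alongside volumes. An alternative reading — choosing the globally
largest cross-section over all three planes first — is possible; the
axial-maximum rule is used because the extracted plane is axial either
way.

## Texture parameters

* **GLCM**: 8 grey levels by uniform binning of [0, 255]; symmetric,
  normalized matrices. The first nine statistics use the 0° offset
  (0, 1); the four "…2" statistics use a single matrix whose pair counts
  are *accumulated* over the 0° and 45° offsets {(0, 1), (−1, 1)}.
  Accumulation (rather than averaging per-offset statistics) is the
  default because it is what "a statistic computed at 0° and 45°"
  usually means operationally; `accumulate_offsets = FALSE` switches to
  averaging. Pooling two directions makes these statistics less
  sensitive to texture orientation, which the test suite verifies on
  stripe patterns. Correlation of a zero-spread (single-cell) matrix is
  defined as 0.
* **HOG**: 8×8-pixel cells, 2×2-cell blocks with stride one cell, 9
  unsigned orientation bins, L2 block normalization; gradients by
  centered differences, one-sided at borders; background pixels zeroed;
  patches are zero-padded to at least 16×16 and to cell multiples. These
  are the descriptor's standard defaults.
* **LBP**: 8 neighbors, radius 1, 59-bin uniform-pattern histogram,
  normalized. Codes are computed for masked pixels only, but background
  pixels (value 0) serve as neighbors at region borders. A consequence
  of normalization is that the `MeanLBP` feature is the constant 1/59;
  on real extracted tables the MAD filter removes it, which is the
  filter doing its job.
* **Shape**: second-moment ellipse descriptors use the per-pixel 1/12
  extent correction; orientation is the major-axis angle in degrees in
  (−90, 90] from the column axis; convex area counts pixels whose
  centers fall inside the hull of mask pixel centers; holes are filled
  by border-connected background propagation (4-connectivity);
  perimeter counts exposed pixel edges times the pixel side length.

## Empty regions

A study may lack an enhancing (or even core) sub-region. The affected
48-feature block is set to 0 (the policy value), the region is recorded
in the `qc_empty_regions` attribute, and the vector stays 147 long so
cohort tables remain rectangular. Joint ratios with an empty denominator
also take the policy value.

# Tunable parameters

| parameter | default | units | where | why |
|---|---|---|---|---|
| month length | 30.4375 | days | `survival_class()` | Julian year / 12; the grouping thresholds are quoted in months but survival arrives in days |
| boundary assignment | 10 and 15 months → MEDIUM | — | `survival_class()` | the medium group is defined inclusively ("between 10 and 15"); the outer groups use strict inequalities |
| quantization rounding | half-up | grey levels | `normalize_mu3sigma()` | deterministic and symmetric on the closed range [0, 255]; a value exactly at μ maps to 128 |
| μ, σ | population (n) denominator | grey units | `normalize_mu3sigma()` | a fixed, documentable convention |
| GLCM levels | 8 | levels | `glcm_matrix()` | the convention of the feature set's original computing environment; configurable |
| λ grid | 100 points, min ratio 0.001 | — | `lasso_select()` | conventional and reproducible; λ_opt (CV minimum) selects, λ_1se is reported |
| CV folds | 10 (selection), 5 (benchmark) | — | | matching the two stages' designs |
| SVM kernel scale | √P (medium), 4√P (coarse) | — | benchmark | the named configurations; `gamma = 1/s²` converts to the RBF parameterization; box constraint C = 1 |
| KNN | k = 100 coarse; k = 10 medium/cosine | — | benchmark | the named configurations; Euclidean unless cosine is named |
| ensemble | 200 LDA learners, subspace ⌈P/2⌉ | — | benchmark | "a few hundred learners" fixed at 200 for reproducibility; a shrinkage learning-rate has no role in subspace ensembles, so none is used |

# The cohort split

With records sorted ascending by survival (stable ties broken by patient
id), every third record joins the validation set and the rest form the
discovery set — a 2:1 split that represents the whole survival range in
both cohorts. For 163 patients this gives 109 discovery and 54
validation. `split_discovery_validation()` refuses unsorted input rather
than silently sorting, so the tie-break is always explicit.

# The synthetic-data design

The generators exist so every stage can be tested without any imaging
accession. They emulate exactly the statistical structure the analysis
relies on, and nothing more:

* **Phantom studies** (`generate_phantom_study()`): nested ellipsoids
  (AT ⊆ TC ⊆ WT) inside an ellipsoidal brain on a 64×64×48 grid at 1 mm;
  BRATS-style labels (edema 2, necrosis/non-enhancing core 1, enhancing
  tumor 4); per-channel, per-region contrast offsets; a checkerboard
  texture of configurable amplitude and period inside the tumor (chosen
  because its co-occurrence statistics are analytically predictable);
  additive Gaussian noise. Every generator is a pure function of its
  configuration and seed.
* **Cohorts** (`generate_cohort()`, `generate_feature_cohort()`):
  survival is drawn from an exponential proportional-hazards model —
  the rate at linear predictor 0 is scaled so the baseline median OS is
  362 days, and the log-hazard is a linear combination of designated
  generating features (standardized, so effect sizes read per SD). The
  exponential is the simplest noise model consistent with a Cox
  analysis and has a single parameter to document. No censoring is
  generated by default, matching the fully-observed treatment of OS; a
  `censoring_frac` flag exists for robustness experiments. Ages are
  N(60, 12²) truncated to [18, 90]; resection status is GTR/STR/MISSING
  with a 49% missing fraction — missingness is an explicit third
  category, mirroring how such cohorts report it, not absent rows.

What the phantoms deliberately do **not** model: MRI physics (bias
fields, partial volume, k-space artifacts), non-ellipsoidal tumor
geometry, inter-scanner heterogeneity, or any claim about the
distribution of real BRATS images. Passing tests therefore demonstrate
that the pipeline's operations are correct and that its estimators
recover planted parameters under the stated generative model — they do
not certify clinical performance on real cohorts, which depends on the
external data.

# Numerical choices and degenerate inputs

* Standardization errors out on σ = 0 over the brain (a degenerate
  volume) rather than dividing by zero.
* `glcm_matrix()` raises a degenerate-texture error when no masked pixel
  pair exists under any offset (e.g. a single-pixel region); inside
  `extract_features()` that block falls back to the empty-region policy.
* Zero-spread inputs define skewness and kurtosis as 0; a constant
  covariate is an error in `fit_cox()` (the information matrix would be
  singular) and a zero-SD column is an error in `zscore_matrix()`.
* LASSO features are standardized internally before penalization;
  coefficients are reported on the original scale, so multiplying a
  column by 10 cannot change the kept set.
* Cross-validation folds are stratified by survival class and globally
  balanced (sizes differ by at most one); all fold assignments derive
  from the supplied seed. In the benchmark, each feature configuration
  shares one fold assignment across all eight classifiers so that
  classifier comparisons are paired.
* All per-fold preprocessing (centering/scaling) is fit on the training
  part of the fold only; zero-spread columns get scale 1.
* The subspace-discriminant ensemble skips a learner whose random
  subspace is degenerate for LDA rather than failing the whole fit.
* Multiclass SVM scores come from the one-vs-one decomposition as
  pairwise vote counts plus the summed signed margins squashed into
  (0, 1) as a tie-break. Summing raw margins alone is not robust — a
  pair that does not involve a sample's true class can contribute an
  arbitrarily large irrelevant margin — while pure votes are too
  discrete for ranking AUCs; the combination keeps the argmax equal to
  the vote winner and the scores continuous.

# Problem sizes in the test suite

The suite exercises parameter recovery at sizes chosen to make the
statistical checks sharp but quick: LASSO support recovery on n = 300
with 147 columns over 50 seeds; Cox coefficient recovery for a binary
hazard-ratio-2 covariate at n = 500 over 50 seeds; classifier sanity on
150 well-separated points and 200 label permutations; and texture-oracle
equivalence on 100 random 8×8 patches. Imaging-level tests use the
64×64×48 phantom, for which full extraction takes well under a second
per study.

# Known limitations

* Feature index numbering interacts with block order; the shipped order
  (WT, AT, TC) is fixed by `feature_manifest()` and should be treated as
  part of the signature's identity — scores are meaningless if features
  are reordered between fitting and prediction (names, not positions,
  are used everywhere for safety).
* The Gaussian-LASSO selection stage ignores censoring by construction;
  with censored data use `family = "cox"` in `lasso_select()` /
  `radiomics_signature()`.
* The half-median cutoff rule requires the short-group median score to
  exceed the long-group median; on a cohort where the signature fails to
  order the groups, `derive_cutoffs()` raises an inverted-cutoff error
  instead of producing a nonsensical stratification.
* 3-D texture matrices, filtered (wavelet/Laplacian) features and
  IBSI-complete compliance are out of scope; the catalogue is fixed at
  the 147 features described above.
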
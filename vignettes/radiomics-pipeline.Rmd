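---
title: "Methods: multi-sequence MR radiomics for two-class lesion discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sequence MR radiomics for two-class lesion discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionrad)
```

## The problem and the model

Hepatocellular carcinoma (HCC, malignant) and hepatic haemangioma (HH,
benign) can look alike on precontrast MRI, and contrast injection is not an
option for every patient. The radiomics approach replaces visual assessment
with a high-throughput quantitative one: segment the lesion on four
precontrast sequences (in-phase and out-phase T1, T2-weighted, and
diffusion-weighted images), extract a large bank of intensity, texture and
shape descriptors per sequence, reduce them to a small signature, and train
standard classifiers whose held-out ROC behaviour is the evidence.

This package implements that pipeline end to end, with a synthetic
lesion-phantom generator standing in for patient data (none are deposited
with the study the pipeline emulates). The processing chain per lesion and
sequence is:

1. **Normalization.** Whole-volume z-scoring, `f(x) = s (x - mu_x) / sigma_x`
   with `s = 1` by default. The source description calls `sigma` "the
   variance", but only the standard deviation makes `f` unit-variance, which
   is the evident intent of the formula; we use the population SD (at
   whole-volume voxel counts the sample/population distinction is
   negligible). Statistics are whole-image, not ROI-restricted, since the
   formula is stated for "the image". Normalization makes every downstream
   texture feature invariant to scanner gain and offset, which the test
   suite asserts end to end.
2. **Discretization.** In-mask intensities are mapped to `Ng = 32`
   equal-width grey levels spanning the in-mask range (the top value maps to
   level `Ng`). A fixed *bin count* rather than a fixed bin width is the
   meaningful choice after z-scoring, where absolute widths have no units. A
   constant ROI degenerates to a single level with a warning and the
   documented degenerate-feature conventions below.
3. **Feature bank (1029 per sequence).** 93 original features - 19
   first-order, 15 shape, 27 GLCM, 16 GLRLM, 16 GLSZM - plus the 78
   intensity-dependent features (shape excluded: filtering does not move the
   mask) recomputed on 12 filtered variants of the normalized volume:
   exponential, square, square root, logarithm, and the 8 single-level 3-D
   wavelet bands; `12 x 78 = 936`.
4. **Selection cascade.** Variance threshold (0.8) -> univariate
   Mann-Whitney filter (keep `p <= 0.05`) -> linear LASSO with
   cross-validated penalty, per sequence. Stages only remove features
   (subset chain asserted).
5. **Classification.** Decision tree, random forest, k-nearest-neighbours
   and logistic regression per sequence and on the combined model
   (concatenation of all sequences' selected features), evaluated by AUC,
   and sensitivity/specificity at the Youden-optimal threshold on a held-out
   20% test side; AUC differences are tested with DeLong's method for
   correlated curves.

## Texture definitions and conventions

All second-order statistics use the 13 unique directions of the 3-D
26-neighbourhood at distance 1 voxel, the most common convention and one
closed under 90-degree grid rotations (so direction-averaged features are
rotation-stable, which is tested). GLCMs are symmetrized (`A + t(A)`) and
normalized; GLRLM runs are maximal same-level runs restricted to in-mask
voxels; GLSZM zones are 26-connected equal-level components (no directions).
Every matrix implementation is checked against an independent brute-force
enumerator (pair counting, run walking, flood fill) on randomized ROIs.

Two GLCM names in the emulated feature list are non-standard;
`AverageIntensity` is mapped to the joint grey-level average and
`GrayLevelIntensity` to the joint grey-level variance. The latter therefore
coincides with `SumOfSquares`, just as `Homogeneity1`/`InverseDifference`
and `Homogeneity2`/`InverseDifferenceMoment` coincide under the standard
definitions; all are kept as separate registry entries because the source
taxonomy lists them separately. The GLSZM entry "Gray Level Non-Normalized"
is read as Gray Level Non-Uniformity Normalized (an evident truncation).

**Degenerate conventions.** A constant ROI gives: entropies 0, `Uniformity`
and `MaximumProbability` 1, distance-type GLCM features 0,
correlation-type features 1, and skewness/kurtosis 0, always with a
degeneracy flag. A single-voxel mask has no co-occurrence pairs: its GLCM
features are 0 and flagged. These conventions keep the pipeline total on
edge cases without silently producing NaN.

## Shape features and the surface mesh

`Volume` is voxel count times physical voxel volume; axis lengths are
`4 sqrt(lambda_i)` from the eigenvalues of the physical-coordinate
covariance of mask voxels, with `Elongation = sqrt(lambda_2/lambda_1)` and
`Flatness = sqrt(lambda_3/lambda_1)` (1 for a ball; 0 for a point or
degenerate object, the stated boundary semantics).

Surface area needs care on binary grids. A raw triangulated 0.5 iso-surface
of a binary mask - marching cubes included - systematically overestimates
the area of smooth objects because of staircase facets: for a digital ball
of radius 10 the overestimate is around 9%, pushing sphericity to about
0.91, outside any reasonable tolerance around 1. We therefore mesh the
voxel-face boundary (watertight by construction) and apply 20 iterations of
Taubin lambda-mu smoothing (`lambda = 0.5`, `mu = -0.53`), a standard
shrinkage-free mesh fairing; measured sphericity of digital balls of radius
6-14 then lies within 1-3% of 1. Masks under 27 voxels keep the raw face
mesh - smoothing collapses tiny meshes - so a single voxel reports exactly
the unit voxel cube, as required. Maximum 3-D/2-D diameters are the largest
pairwise distances between boundary-voxel centers (in 3-D and in the plane
orthogonal to the column or row axis).

## Filtered variants

The four pointwise maps are sign-preserving strict monotone bijections of
`[-M, M]` onto itself, `M = max |x|`: square `s(x) = sign(x) x^2 / M`,
square root `sign(x) sqrt(|x| M)`, logarithm
`sign(x) M ln(|x|+1)/ln(M+1)`, exponential `sign(x)((M+1)^{|x|/M}-1)`. The
source names the filters but not their scalings; these forms map `0 -> 0`
and `+/-M -> +/-M` so filtered volumes stay on the input scale, and the
square/square-root pair are exact inverses (tested to 1e-9).

The wavelet bank is a single-level separable 3-D Coiflet-1 decomposition.
We use the *undecimated* (stationary) transform with periodic boundaries so
every band lives on the original grid and the lesion mask applies without
any half-resolution interpolation; per-axis filters are scaled by
`1/sqrt(2)` so the LLL band has unit DC gain (it is a smoothed copy of the
input, and its in-mask mean tracks the original) while H-containing bands
annihilate constants. Band letters follow axis order (x, y, z). The
orthonormal decimated variant is kept internally and verified by a Parseval
check on dyadic grids. The basis, decimation choice and scalings are
configuration-recorded; the source states none of them. Because the
Coiflet-1 filter is asymmetric, wavelet-band features are the one part of
the bank that is not exactly equivariant under 90-degree rotations (which
embed a reflection); the rotation-invariance tests therefore cover the
original and pointwise-filtered features.

## Selection cascade: scales and tests

The 0.8 variance threshold operates on **raw** sample variance (the
`VarianceThreshold` semantics of the scikit-learn lineage), keeping features
with variance `>= 0.8`. A proposed alternative - thresholding after
rescaling features to [0, 1] - is self-defeating: a bounded variable has
variance at most 0.25, so a 0.8 threshold would remove everything. The raw
scale is also the only one consistent with the chi-square calibration the
test suite checks (standard-normal features pass at the
`P(S^2 >= 0.8)` rate).

The univariate stage uses the two-sided Mann-Whitney U test (the source
does not name its test; Mann-Whitney is distribution-free and standard in
radiomics), keeping `p <= 0.05` with no multiple-testing correction - a
faithful but deliberately liberal pre-filter. Its type-I behaviour under
label permutation (about 5% of null features kept) is part of the
acceptance suite.

The LASSO is linear (least-squares on the 0/1 label), matching the
"optimal alpha" framing of the emulated workflow; the penalty that
minimizes subject-grouped 5-fold cross-validated MSE is reported as
`alpha` (identical to glmnet's `lambda` for this objective). Features are
standardized internally so coefficients are comparable. At zero penalty the
fit reproduces ordinary least squares (tested against the closed form);
at large penalty it selects nothing, which propagates as a valid empty
selection - downstream model cells for that sequence are recorded as
unavailable rather than silently dropped.

## Classifiers, split, and evaluation

The emulated study fixes no hyperparameters, so this package fixes and
documents its own: CART decision tree (Gini, depth <= 5, minimum split 4);
random forest of 100 bagged CART trees (depth <= 10, `mtry = sqrt(p)`),
scored by mean leaf class-1 proportion; KNN with `k = 5` on standardized
features, scored by neighbour vote fraction; ridge-penalized logistic
regression with penalty `1/n` (the unit-regularization convention). All are
deterministic under a seed. None of the four is taken from an external
tree/forest package because none is available in the dependency set; the
CART core is purpose-built and exercised against separable and planted-
effect cases.

The 80/20 split is random, class-stratified, and *subject-grouped*: the
emulated cohort has more lesions than patients, and splitting lesions of
one patient across train and test would leak. This is a deliberate,
documented strengthening of the literal "randomly selecting 80% of the
samples"; the literal lesion-level split is available behind
`group_by_subject = FALSE`. Selection and classifier fitting see training
rows only; the suite asserts bit-identical training artifacts when test
labels are shuffled under a fixed split.

The combined model concatenates each sequence's selected features into one
vector per lesion ("combining four sequences" is all the source states).
Operating points maximize the Youden index with ties broken toward higher
sensitivity. DeLong's variance estimate is validated against a bootstrap on
synthetic scores.

## The phantom generator: what it emulates, and what it does not

`phantom_spec()` freezes a stated world mirroring the emulated cohort's
geometry: 369 subjects, 1-3 lesions each (geometric decay, mean about 1.2,
for about 446 lesions), near-balanced classes, anisotropic 1 x 1 x 5 mm
voxels matching the 5-mm slice thickness. Lesion sizes are not reported in
the source, so the 5-15 mm semi-axis range is a generator choice typical of
reported liver-lesion series, fixed once. Lesions are lobulated ellipsoids
(low-order angular perturbation of the radius, amplitude up to 0.2) on a
Gaussian-noise background over a smooth low-frequency bias field - the bias
is what makes the normalization stage consequential. Class 0 ("HH-like")
lesions are homogeneous and T2-bright; class 1 ("HCC-like") lesions
additionally receive per-sequence mean shifts (defaults: +0.5, +1.0, -1.5,
+0.8 noise-SD units on in-phase, out-phase, T2WI, DWI) and a heterogeneity
texture: a Gaussian random field smoothed at a 2-voxel scale, scaled by
`(heterogeneity - 1)` noise-SD units, added inside the mask. The multiplier
is neutral at 1, the null spec (`null_effects()`) makes the classes
bit-identical, and within-mask variance is strictly monotone in the
multiplier (Monte-Carlo tested). The "multiplicative" heterogeneity knob is
implemented additively in SD units so that its variance effect is
analytically controllable.

What a green test does **not** establish: the phantoms contain no organ
anatomy, partial-volume effects, motion or registration error, scanner
field-strength differences, or realistic lesion-class texture beyond the
planted first-order and smoothed-field structure. In particular, reaching
a given AUC on phantoms says nothing about patient-data AUCs; the emulated
study's Table of results is context, not a target, and the acceptance
criteria are structural (feature-bank cardinalities) and property-based
(oracle equivalence, closed forms, planted-effect recovery, null
calibration, invariances).

For selection/classifier testing there is also a tabular counterpart,
`simulate_feature_table()`, which plants a configurable number of
informative standard-normal features (standardized effect 2.0 by default)
among noise features - this is the cohort on which recovery and null
calibration are measured, at the sizes the acceptance criteria state
(n = 200 lesions, 100 features, 3 informative per sequence, 20 seeds).

## Numerical choices and edge cases

- Percentiles use linear interpolation (R type 7); moments are population
  moments; kurtosis is not excess-corrected.
- The first-order `Entropy`/`Uniformity` histogram reuses the texture
  discretization bin count.
- NIfTI I/O is a minimal NIfTI-1 implementation (no R NIfTI package is
  available in the dependency set): float64 volumes, uint8 masks, spacing
  from `pixdim`, masks binarized at > 0.5, strict 3-D-ness, and loud
  failures on shape or spacing mismatches - there is no silent resampling
  anywhere.
- Feature tables round-trip CSV at full double precision (`data.table`).
- Seeds: every stochastic step (cohort draw, per-lesion fields, fold
  assignment, bootstrap, split) is derived from configuration seeds kept
  below 2^31.
- Scaled-down test sizes: image-level null-calibration and
  effect-monotonicity checks run on reduced grids (14^3-ish, one sequence,
  original features only) to keep the suite within minutes; the tabular
  cohorts run at the stated n = 200 x 100 x 4 sizes.

## Known limitations

- Wavelet-band features depend on the (documented) boundary handling and
  filter alignment; other packages' wavelet radiomics will differ
  numerically.
- The surface-area estimator is calibrated for blob-like lesions; for
  needle-like or single-slice masks the unsmoothed mesh bound applies.
- Mixed-class subjects (possible in principle, not produced by the
  generator) are stratified by their first-seen label.
- The univariate stage is intentionally uncorrected for multiplicity,
  faithful to the emulated protocol; interpret per-sequence survivor counts
  accordingly.
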
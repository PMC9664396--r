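---
title: "Methods: the large-nodule radiomics signature and decision support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the large-nodule radiomics signature and decision support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnrpv)
```

## The problem and the model

Incidentally detected large lung nodules (15–30 mm) carry the highest
malignancy risk of any nodule size class, yet the clinical risk models in
routine use stratify them poorly: almost every large nodule crosses the
10% Brock threshold that triggers work-up, and a large fraction lands in
the intermediate (10–70%) band of the Herder score, where guideline
options range from surveillance to surgery. `lnrpv` implements a
two-feature CT radiomics signature for this size class, the surrounding
development and evaluation machinery, and the decision rule that uses the
signature to sharpen management within the intermediate Herder band.

The signature, the **large-nodule radiomics predictive vector (LN-RPV)**,
is a linear score on two z-standardised features:

$$\mathrm{LN\text{-}RPV} = -0.5143257 \, z(\mathrm{SNS\_s2v})
 + 0.1840902 \, z(\mathrm{GLCM\_Correl})$$

* **SNS_s2v** — the nodule's surface area divided by its volume
  (mm^-1). Rounder, bulkier nodules have lower surface-to-volume ratio;
  the negative weight means they score as higher risk.
* **GLCM_Correl** — the correlation of the grey-level co-occurrence
  matrix (GLCM), a measure of the linear dependency between neighbouring
  voxel intensities; spatially coherent internal texture raises the
  score.

A score at or above the fixed operating threshold **−0.1991184** (the
training-set Youden optimum; the boundary is inclusive by our convention,
consistent with the sensitive operating point the threshold encodes)
calls the nodule malignant. For decision support the continuous score is
additionally split into *low*/*high* risk groups by 1-D K-means
clustering of training scores (the cluster with the larger centroid is
"high"; held-out scores are assigned to the nearest training centroid,
ties to "high").

## Image processing chain

1. **Read** NIfTI image/mask pairs (`read_volume()`); volumes are
   reoriented to canonical RAS axes when the file carries a full affine,
   so "axial" always means the third array axis. Masks binarise as
   value > 0. Image/mask alignment is accepted when spacings agree
   within 10^-3 mm (real exports carry float jitter).
2. **Resample** to 1 × 1 × 2 mm (`resample()`): separable natural cubic
   splines for images, nearest neighbour for masks (masks stay binary).
3. **Cap** intensities to [−2000, +2000] HU (`cap_intensities()`).
   Capping is applied *after* resampling so spline overshoot is clamped
   too; the output range therefore holds at feature-extraction time.
4. **Crop** to the mask bounding box (`crop_to_mask()`), default margin
   0 — features are mask-restricted, so cropping only affects run time.

## Feature definitions and numerical choices

* **Quantisation**: fixed 25-HU bins anchored at the in-mask minimum
  (`level = floor((I − min)/25) + 1`). Adding a constant to every voxel
  leaves levels unchanged; a flat region maps to a single level.
* **GLCM**: symmetric (counts plus transpose), distance 1, all 13 unique
  3-D offsets, computed in voxel steps on the working 1 × 1 × 2 mm grid
  (not physical-distance matched — the convention of mainstream
  extractors). The feature is the unweighted mean of per-offset
  correlations over non-empty offsets. A degenerate GLCM with zero
  marginal variance (flat region) has correlation 1 by convention; this
  is documented, testable behaviour rather than an error.
* **Surface mesh**: the zero-padded binary mask is triangulated with
  marching tetrahedra at level 0.5 and relaxed with 60 Taubin
  (λ = 0.5, μ = −0.53) smoothing passes. Raw binary iso-surfaces carry
  voxelisation creases that inflate curved areas by 10–20%; Taubin
  relaxation removes the creases without shrinking the mesh, so flat
  faces stay essentially exact (a 10 mm cube at 0.5 mm voxels measures
  within ~3% of 600 mm²) while a 10 mm-radius sphere at 0.5 mm voxels
  lands within ~3% of the analytic area. At the anisotropic working
  spacing a residual positive area bias of a few percent remains (z
  staircase); all signature uses at that spacing are relative
  comparisons, which the bias does not reorder.
* **Max axial diameter**: largest in-plane Feret diameter over axial
  slices (convex hull of voxel centres, plus one mean in-plane voxel
  extent for the finite voxel footprint).
* **Standardisation**: z-scores use training-set means and sample SDs
  only; held-out data are transformed with the *training* statistics.
  Whether pooled or training-only scaling was used upstream is not
  determinable; training-only is the leakage-free choice.

## Clinical calculators

`brock_probability()` implements the Brock (PanCan) *full model with
spiculation* — the variant recommended by the British Thoracic Society
pathway — and `herder_probability()` the Herder PET-adjusted model with
ordered FDG-avidity categories (absent < faint < moderate < intense).
Both coefficient sets are transcribed verbatim into
`inst/extdata/clinical_model_coefficients.csv` with a citation per line;
that file is the single source of truth read at run time. Records with
no PET study are imputed PET-negative (`impute_pet()`, flagged, and
idempotent). The cohort schema's `lung_disease` field maps to the Brock
emphysema covariate — the closest recorded field, documented as an
approximation.

## Signature development workflow

`develop_signature()` reproduces the development pipeline:

1. **Grouped stratified split** (`grouped_stratified_split()`): patients,
   not scans, are allocated 70/30 with class stratification, so multiple
   scans of one patient can never straddle the split.
2. **Univariable screen** (`univariable_screen()`): per-feature logistic
   fits, Wald z-tests, Benjamini–Hochberg step-up adjustment across the
   screened family, selection at adjusted p < 0.05. Non-converged
   (perfectly separating) features are flagged and excluded with a
   warning.
3. **LASSO** (`lasso_signature()`): penalised logistic path via glmnet
   over ~100 log-spaced lambdas spanning a 10^-4 ratio, 10-fold CV with
   class-stratified folds (the fold seed is explicit), binomial
   deviance, and the `lambda.1se` rule. The intercept is never
   penalised and predictors are assumed pre-standardised — no internal
   rescaling.
4. **Operating point and risk groups**: Youden-optimal threshold on
   training scores (smallest threshold among ties) and 1-D K-means risk
   clusters with 25 restarts.

Wald (not likelihood-ratio) p-values are used throughout, matching the
stated univariable/multivariable testing. `vif()` reports
1/(1−R²) per predictor for collinearity triage; exact collinearity is
`Inf` with a warning, not an error, because dropping the offender is the
expected response.

## Evaluation statistics

* **AUC** is the Mann–Whitney statistic with half credit for ties, so
  ordinal reader scales are handled exactly; CIs are percentile
  bootstrap (default B = 1000, seeded), resampling scans — or patients
  when ids are supplied, since cohorts carry up to three scans per
  patient. Percentile rather than BCa because only the iteration count
  of the upstream procedure is known.
* **DeLong** paired AUC comparison via placement-value covariance;
  identical score vectors return z = 0, p = 1 exactly.
* **Accuracy CI** is a Wilson interval — well-behaved at a few hundred
  scans; rates with zero denominators are `NA`, never silently 0.
* **ICC(A,1)**: two-way random-effects, absolute-agreement,
  single-measurement ICC from the mean-squares decomposition, with the
  F-based p-value (F = MSR/MSE on (n−1), (n−1)(k−1) df).
* **Kruskal–Wallis** wraps `stats::kruskal.test` (tie-corrected H,
  chi-square p); **Dice** is 2|A∩B|/(|A|+|B|), defined 1 when both
  masks are empty.

## Decision support

`recommend()` applies the published integration rule for solid nodules:
Herder < 10% → surveillance; 10–70% with low LN-RPV → standard work-up;
10–70% with high LN-RPV → **upgrade to early intervention**; > 70% →
high-risk pathway. Band edges 10 and 70 belong to the intermediate band
(the rule is written "10–70%" without edge conventions; ours are
documented and tested). The radiomics score only ever prompts *earlier*
intervention — it never downgrades. Non-solid input returns standard
work-up with a scope warning rather than an error, so mixed cohorts
flow through the pipeline. `cross_tabulate()` and `upgrade_summary()`
produce the band × risk × outcome table (restricted to Herder ≥ 10%)
and its headline percentages.

## What the synthetic generators emulate — and what they do not

`generate_phantom()` builds spheres or spiculated shapes (sphere plus
radial cones at quasi-uniform Fibonacci-sphere directions — reproducible,
parameterised spiculation) with analytically known volume, area and
diameter, filled at soft-tissue HU inside an aerated-lung background.
`generate_textured_phantom()` overlays Gaussian noise smoothed to a
chosen correlation length *before* masking, so boundary voxels share the
field's autocorrelation and GLCM tests see no edge artefact; the field
is rescaled to the requested SD after smoothing. Correlation length 0
gives white noise, for which neighbouring voxels are independent and
GLCM correlation is near 0.

`simulate_cohort()` draws patient covariates from the marginals of the
multi-centre large-nodule population the package targets (62.5%
malignancy, 70.6/22.8/6.6% solid/subsolid/GGO, 23.9% spiculation, age
69 ± 10, size 20.5 ± 4.7 mm truncated to 15–30 mm, smoking and PET
mixes as recorded; upper-lobe location, not tabulated upstream, is set
to 50%, and the 1–3 scans per patient are drawn 0.50/0.32/0.18 to give
the recorded ≈1.68 scans/patient), then assigns one malignancy label
per patient from a logistic model with user-chosen effects — the final
diagnosis defines the ground truth for all of a patient's scans.
Simulated effect sizes are free parameters, not estimates of any real
cohort.

None of this simulates lung parenchyma, vessels, scanner kernels or
reconstruction noise. Passing tests therefore demonstrate that the
*computational machinery* is correct (features match analytic and
brute-force oracles; estimators recover known generative parameters) —
not that the published discrimination transfers to real scans, which
requires the original patient data.

## Problem sizes used in the test suite

Simulation-backed tests run at deliberately modest, fixed-seed sizes
chosen to keep the full suite under a minute while leaving comfortable
statistical margins: GLCM oracles on ≤ 14×12×10 grids; parameter
recovery at n = 5000; LASSO support recovery at n = 2000, p = 50 over
10 reseeds (≥ 8 must recover both true features); null-uniformity of
DeLong and Kruskal–Wallis at 500 replicates; bootstrap CI coverage at
500 replicates of B = 200 resamples (95% ± 3 points).

## Known limitations

* The Herder coefficient table follows the widely reproduced published
  parameterisation; its PET-absent calibration is tied to the original
  high-prevalence surgical cohort, so absolute Herder percentages run
  high in low-risk profiles. All monotonicity properties hold and are
  tested.
* The binning anchor, offset set and aggregation of the original
  in-house feature extractor are unpublished; our conventions are
  standard and documented, but numeric equality with the original
  feature spreadsheets is not guaranteed.
* Wavelet/filtered features, GLRLM/GLSZM/NGTDM families and deep-learning
  segmentation are out of scope; auto-segmentation enters only through
  the Dice metric.
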
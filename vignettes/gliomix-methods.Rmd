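---
title: "Methods: integrated qualitative and quantitative MRI analysis for glioblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated qualitative and quantitative MRI analysis for glioblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

Glioblastoma prognosis varies widely even within the IDH-wild-type group, and
molecular markers (MGMT methylation, EGFR amplification, IDH1 mutation) are
only available after tissue sampling. `gliomix` implements a complete,
reproducible analysis chain that combines three information blocks from
routine pre-operative MRI — qualitative VASARI scores, quantitative radiomics
features from co-registered T1+Gd and T2-weighted volumes, and clinical
covariates — into (i) a stacked Cox prognostic model for overall survival
with external-validation diagnostics, and (ii) machine-learning classifiers
for the molecular markers. Because real patient volumes cannot be shipped,
the package includes a synthetic multi-scanner cohort generator with known
ground truth; every statistical property of the pipeline is demonstrated by
parameter recovery on cohorts whose generating mechanism is recorded.

## The synthetic cohort generator

Each patient is an ellipsoidal tumor phantom on a scanner-specific grid:

* **Geometry.** An enhancing tumor with semi-axes drawn log-normally around
  13 x 11 x 9 mm, a necrotic core (semi-axis fraction uniform on 0.3–0.7), and
  a T2 edema halo (semi-axis multiplier uniform on 1.15–1.75). A second
  lesion appears with probability 0.2 and sets the multifocality flag, so
  qualitative scores and image content correlate as in real data. T1 and T2
  are generated on one grid (co-registered by construction), hence the
  T2 tumor/edema mask always contains the T1 enhancing mask.
* **Tissue model.** Piecewise-constant levels per modality (T1: background
  0.30, rim 1.00, core 0.15; T2: background 0.25, tumor 0.55, edema 0.85),
  multiplied by a smooth bias field — a product of per-axis quadratics with
  random coefficients, normalised to mean 1, amplitude bounded by the scanner
  profile — plus i.i.d. Gaussian noise. Gaussian rather than Rician noise is
  a deliberate simplification: at the simulated contrast-to-noise levels the
  Rician correction is negligible and the Gaussian keeps every preprocessing
  identity exact.
* **Scanner heterogeneity.** Training and validation cohorts draw from
  different mixtures of scanner profiles (pixel spacing 0.7–1.1 mm, slice
  thickness 5–6 mm, bias amplitude 0.15–0.30, noise 0.02–0.04), emulating two
  independent multi-centre datasets.
* **Outcomes.** Survival times are exponential with hazard
  `baseline_hazard_rate * exp(sum(beta * x))` over named latent features
  (tumor volume, multifocality, subependymal extension, edema category,
  adjuvant regimen, age group); censoring is independent exponential. The
  default baseline puts the median survival of a reference patient at 12
  months, the scale of the disease. Markers are Bernoulli draws from logistic
  models over the same latent features. The full generating parameter set
  (`ground_truth()`) is serialised next to every cohort, and one master seed
  makes cohorts byte-identical across runs.
* **Default cohort sizes** are 142 and 46, the scale of a two-centre
  retrospective glioblastoma series; tests and examples use smaller cohorts
  chosen for their statistical purpose and stated at each call.

What the generator does **not** emulate: anatomy (no brain, skull or
ventricles), registration error between sequences, Rician noise, motion or
ghosting artefacts, and inter-observer delineation variability. Passing
tests therefore demonstrate correctness of the *analysis machinery* and
recoverability of planted signal under realistic acquisition heterogeneity —
not clinical performance on real cohorts.

## Preprocessing

Steps run in a fixed order: resample → bias-correct → equalize → Z-score.

* **Resampling.** In-plane interpolation is cubic convolution over a 4x4
  sample neighbourhood (Keys kernel, a = −0.5), which reproduces affine
  intensity ramps exactly; through-plane interpolation is linear because
  cubic kernels overshoot across thick (5–6 mm) slices. The default target
  grid is the per-axis mode of the training cohort's spacing distribution
  (minimising the number of resampled images); a fixed reference geometry of
  0.449 mm in-plane / 5.5 mm through-plane is the function default when no
  cohort is in scope.
* **Bias-field correction.** The low-frequency multiplicative field is
  estimated by robust regression in the log domain: an additive per-axis
  polynomial (degree 4) fitted by IRLS with Tukey bisquare weights, so
  anatomy-driven outliers (the tumor) do not drag the field. The image is
  divided by the exponentiated zero-mean field; non-positive images are
  shifted before the log and shifted back after, with the shift recorded. A
  degenerate fit returns the input unchanged with an explicit flag, never
  silently.
* **Histogram equalization** is global: each voxel maps through the volume's
  empirical CDF, giving values in (0, 1] and preserving rank order. It is
  applied to the whole volume, not mask-restricted — the delineation should
  not influence the intensity frame. Consequence (used as a test): the
  equalize→Z-score tail of the chain is invariant to any strictly monotone
  intensity warp of the input.
* **Z-score transfer.** `mu`/`sigma` are the mean and population standard
  deviation of the *pooled training voxels after the previous steps* (so the
  published frozen values for a given study are taken to be post-equalization
  parameters), estimated once per modality and transferred unchanged to
  validation. On the training pool itself the transform recenters exactly; on
  a validation cohort it deliberately does not.

## Radiomics features

Per modality, features are computed on the original image and on each
derived image of the filter bank, with shape computed once on the original
mask geometry. Feature ids follow
`{modality}_{filter}_{class}_{name}`.

* **Filter bank.** Laplacian-of-Gaussian at physical scales 2, 3, 4, 5 mm
  (sigma converted to voxels per axis; responses scale-normalised by sigma²,
  so blob structure at the filter's scale gives the extremal response), and a
  single-level undecimated 3D wavelet decomposition. The wavelet family is
  Coiflet-1 with filters normalised to unit DC gain, mirror-extended
  boundaries; sub-band labels follow axis order (x, y, z). Both operators are
  linear, annihilate the appropriate low-order signals, and are
  config-overridable.
* **Discretization** uses a fixed count of 32 equal-width bins over the
  in-mask intensity range. Since inputs are Z-scored, a fixed bin *width*
  would be unit-dependent; 32 bins is a common choice for MR radiomics.
* **Texture matrices.** GLCM: distance 1, the 13 unique 3D directions,
  symmetric, features computed per direction and angle-averaged. GLRLM: runs
  per the same 13 directions, averaged the same way. GLSZM: 26-connected
  equal-level zones. GLDM: 26-neighbourhood, dependence threshold alpha = 0,
  dependence size = the voxel plus its equal-level in-mask neighbours.
  NGTDM: 26-neighbourhood means. On single-slice input the neighbourhoods
  reduce to their 8-connected in-plane counterparts, so 2D worked examples
  evaluate exactly.
* **Numerical conventions.** Percentiles use the linear-interpolation
  quantile definition; skewness and kurtosis are population moments; features
  undefined on a region (correlation-type features at a single gray level,
  dispersion ratios on constants, NGTDM on a region with no valid
  neighbourhood) are flagged `NA` with a reason in the manifest and excluded
  from downstream modelling with a logged count — never silently dropped and
  never propagated as `NaN`.
* **Inventory.** The default configuration yields 2438 features per patient
  (2 modalities x 13 derived images x (19 first-order + 74 texture) + 2 x 10
  shape). The inventory is configuration-driven; the manifest written beside
  every extraction is the authoritative enumeration. Whether shape features
  enter the prognostic/predictive candidate pools is a configuration flag
  (default: they are extracted and eligible).
* **Verification.** Every matrix class and every scalar feature is checked
  against an independent brute-force implementation (naive nested loops) on
  random 5x5x3 regions to 1e-12, plus closed-form worked examples.

## VASARI block

The schema declares each qualitative item with its category set; raw
multi-categorical scores are collapsed by a versioned recoding map
(JSON-serialisable data, not code) at clinically natural cut-points — e.g.
edema proportion `none`/`<1/3` → `low` (the reference level), `1/3–2/3` →
`medium`, `>2/3` → `high`. Recoding is idempotent; unknown categories become
missing with a logged count. Modelling consumes a treatment-coded design
matrix (reference levels declared in the schema; ordinal edema expands to
`medium`/`high` indicators), and an unseen level at validation time is a
hard error naming the level. Missing values are handled per model by
complete-case exclusion, so each model reports its own n.

## Prognostic workflow (Models 1–7)

Single-block chains, per block:

1. **Univariate Cox screen** — per-feature Wald p (the test type is a
   package choice; score and LR tests agree to the precision that matters at
   the liberal threshold), keep p ≤ 0.2.
2. **Correlation elimination** — greedy over pairs with |Spearman| strictly
   > 0.85 (a pair at exactly 0.85 is kept); the survivor is the member with
   the smaller univariate Cox p (the prognostic-arm analogue of the
   predictive arm's lower-AUC rule), ties and absent priorities resolved by
   column order. Deterministic.
3. **Multivariable Cox fit** — Efron tie handling (monthly survival times tie
   often), partial-likelihood maximisation via the survival ecosystem.
   The candidate list is capped at events − 1 (best univariate p first), and
   monotone-likelihood covariates are reported by name.
4. **Backward elimination** — refit after each removal of the largest Wald p
   while it exceeds 0.2. The refit variant of "fast backward" is used: at
   these cohort sizes the single-fit approximation saves nothing and the
   refit is exact.

The clinical model enters all covariates (sex, surgery type, age > 70,
non-STUPP adjuvant regimen, MGMT methylation) without elimination. Each
model's prognostic index PI = sum(beta x) is centred at its training mean
(the constant is serialised with the model; PI differences are unaffected).
PIs are centred but not rescaled before stacking — rescaling would change
the printed hazard ratios per score unit without changing discrimination.
Models 4–7 are Cox fits on the component PIs alone, giving one hazard ratio
per score.

**Validation diagnostics** (training-frozen quantities throughout):
Harrell's C with a percentile bootstrap CI over patients (500 resamples by
default; the bootstrap makes no proportional-hazards assumption);
calibration slope = the coefficient of the frozen PI refit on validation,
with a likelihood-ratio test of slope = 1 via the offset model (on training
data the slope is exactly 1 by the score equation — used as a self-test);
the joint misspecification test = Cox fit of the signature's individual
features on validation with the frozen PI as offset, LR-tested against all
zeros; and the Kaplan–Meier split at the training 75th PI percentile with
log-rank test and model-predicted group-average survival curves (per-patient
predicted curves from the PI and the training baseline, averaged within each
risk group, plotted dashed against the observed solid curves). Spearman
correlations against mask-derived tumor volume guard against
volume-surrogate features; cross-block associations use the point-biserial
coefficient for binary-vs-continuous pairs and Spearman otherwise.

## Predictive workflow (molecular markers)

Patients with a missing marker label are excluded first. Per feature block
(VASARI design matrix, radiomics):

1. Correlation elimination (|Spearman| > 0.85) dropping the member with the
   lower univariate ROC AUC (folded above 0.5; ties keep the
   lexicographically smaller id).
2. Z-score normalisation frozen on the modelling cohort.
3. A 70/30 label-stratified split.
4. Cumulative random-forest importance: 1000 forests by default, tree count
   uniform on [20, 300] and depth on [2, 6] per fit, Gini impurity
   importances accumulated; the top 20 features proceed.
5. Randomized search over gradient-boosted trees, random forests and ridge
   logistic regression (the printed tree-count/depth ranges; learning rate
   log-uniform on [0.01, 0.3], subsampling on [0.6, 1], ridge penalty
   log-uniform on [1e-3, 10] are package defaults), 1000 candidates scored by
   test-split AUC.
6. The top 5 candidates are re-evaluated over 10 fresh stratified splits
   ("lucky-split" guard). The importance selection is re-run per split by
   default (`reselect`), with a flag to freeze the first selection; the
   winner is the best mean AUC and is refit on the full modelling cohort
   before external validation.

The VASARI arm for MGMT is pinned to logistic regression; other arms search
all three families. Class imbalance is handled by stratification only, no
resampling. Validation probabilities of the two arms are ensembled by
elementwise averaging; AUCs use the tie-corrected rank (Mann–Whitney)
formulation with 100-iteration percentile-bootstrap CIs (resamples missing a
class are redrawn and counted). Outcome-heterogeneity histograms pair
class-conditional distributions with Mann–Whitney tests, Bonferroni-adjusted
by the number of features and capped at 1.

All randomness in the search derives deterministically from one master seed
(Lehmer-style stream derivation), so every ranking and every split is
reproducible.

## Pipeline and reproducibility

`gx_run()` executes simulate → preprocess → extract → prognostic →
predictive → report from one configuration (list or YAML). Feature
extraction, which dominates runtime, is cached by a content hash of the
configuration sections it depends on. All CSV/JSON artifacts are hashed into
a run manifest; two runs with the same configuration are bit-identical in
those artifacts (plots are excluded from hashing because the PDF container
embeds timestamps). A thin command-line wrapper (`inst/cli/gliomix`) exposes
the stages as subcommands.

## Problem sizes used in the test suite

The suite exercises the pipeline at sizes chosen to make each statistical
property measurable while keeping the whole suite fast to iterate on:
texture oracles on 50 random 5x5x3 regions; bias correction on 50 phantoms
of 40 x 40 x 24 mm; Cox parameter recovery at n = 2000; misspecification-test
uniformity over 200 simulated validations of n = 200; signature retention
over 100 cohorts of n = 1000 with 3 planted and 20 noise features; stacking
gains over 30 train/validation pairs (600/400); importance recovery at
n = 150 with 5 planted among 45 features; bootstrap coverage over 200
replications; and an end-to-end determinism check on a compact 16 + 8 patient
demo configuration. `scripts/acceptance.R` recomputes the same quantities
from scratch under a caller-supplied seed.

## Known limitations

* The bias-correction step assumes a smooth low-order multiplicative field;
  it is not an N4 reimplementation and will not capture high-frequency coil
  profiles. On mixed-tissue masks the interaction between field and tissue
  structure can dominate the region CV in either direction, which is why the
  verification measures homogeneous tissue compartments.
* The feature inventory follows the standard class/filter structure but is
  not guaranteed to enumerate any external tool's exact feature list; the
  manifest is the contract.
* Predicted survival curves use the training-cohort baseline hazard;
  absolute-risk statements beyond group-averaged curves are out of scope, as
  are time-varying covariates and competing risks.
* Synthetic validation shows recoverability, not clinical transportability;
  AUC/C-index values printed by the demo are properties of the generator
  settings, not estimates for any real population.
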
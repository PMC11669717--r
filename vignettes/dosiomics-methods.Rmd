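---
title: "Dosiomics with CT-dose interaction matrices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosiomics with CT-dose interaction matrices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosimix)
```

## The problem

Radiomics mines quantitative features from a patient's CT; dose-volume
histograms summarise the planned radiation dose but discard its spatial
arrangement. For stereotactic body radiotherapy (SBRT) of lung tumors, the
biological effect of treatment plausibly lives in the *interplay* between
the tissue (as imaged) and the dose deposited in it. `dosimix` implements a
dosiomics pipeline built on that idea: it derives a voxelated biologically
effective dose from the physical plan, computes five voxel-neighbourhood
interaction matrices between CT and dose, extracts standardized radiomics
features from four volumes of interest on every matrix, and feeds them to a
feature-selection plus balanced-random-forest stack to predict treatment
failure, with a Fine-Gray competing-risk model for time-to-event analysis.

Because no public cohort accompanies the method, the package ships a
parametric phantom generator; every empirical claim in the test suite and
acceptance script is computed on synthetic phantoms at run time.

## Grids and preprocessing

All per-case matrices live on a common `volume_grid` (values + spacing +
origin + direction). The analysis grid is 1 x 1 x 2 mm; CT and dose are
resampled trilinearly, masks by nearest neighbour, and all matrices are
cropped to the bounding box of the PTV-plus-ring envelope expanded by a
10 mm margin (the margin is configurable; no published value exists).
Distances are always computed in physical millimetres so the anisotropic
z-spacing is honoured; the ring and PTV dilation use an exact separable
Euclidean distance transform to voxel centres rather than iterative
structuring-element dilation.

## Volumes of interest

* **semiGTV** — clinical GTV voxels with CT number in [-550, 2000] HU
  (inclusive at both ends), removing contour-driven inter-observer noise.
* **PTV** — the planning target volume, taken as given.
* **RING** — voxels outside the PTV within 20 mm of the nearest PTV voxel
  centre. Whether the reference distance is surface-to-surface or
  surface-to-centre is not standardised; centre distance was chosen and is
  the documented convention.
* **ISO50** — voxels outside the PTV receiving at least half the
  prescription dose (inclusive threshold on total physical dose).

An empty region (e.g. an ISO50 that vanishes for a very conformal plan) is
flagged; its features are recorded as missing and the case is reported, not
dropped.

## Voxelated biologically effective dose

The linear-quadratic model gives, per voxel,
$$\mathrm{BED} = n\,d\left(1 + \frac{d}{\alpha/\beta}\right),$$
with $n$ fractions and per-fraction dose $d$ = total dose / $n$ (planning
systems export total dose). Voxels inside the PTV are treated as tumor
($\alpha/\beta = 10$ Gy), the rest as late-responding normal tissue
($\alpha/\beta = 3$ Gy); there is no accepted voxel-level model that
modulates $\alpha/\beta$ by electron density, so the binary rule is used.
For the dominant 10 Gy x 5 scheme this yields 100 Gy inside the PTV and
about 216.67 Gy for a normal-tissue voxel receiving the full 50 Gy. BED
always dominates physical dose and reduces to it as $\alpha/\beta \to
\infty$ — both are asserted in the tests.

## Interaction matrices

At every voxel a pair of 3 x 3 x 3 patches (index space, edge-replicated at
borders so the output keeps the input shape) is read from the CT and BED
volumes and summarised by one of:

* **SPEARMAN** — rank correlation of the 27 paired values (average ranks on
  ties; 0 by convention if either patch is constant): local monotonic
  CT-dose association.
* **ENTROPY** — Shannon entropy (bits) of the paired values' joint 8 x 8
  histogram: local co-complexity. "Entropy between two patches" is
  ambiguous; joint entropy was chosen, with an absolute
  marginal-entropy-difference variant behind a switch.
* **JSD** — Jensen-Shannon divergence (base 2, hence in [0, 1]) between the
  two marginal 8-bin histograms: local distributional dissimilarity.
* **WASSERSTEIN** — first-order Wasserstein distance between the two
  empirical distributions, computed as the mean absolute difference of
  sorted samples.
* **MULTIPLY** — the element-wise CT x BED product (no patching).

Histogram-based metrics first min-max normalise each patch over its own 27
values (a constant patch puts all mass in bin 1), then use 8 equal bins;
Wasserstein also operates on normalised values so HU and Gy scales are
comparable (raw-scale option available). The binning scheme is the
pipeline's single largest free parameter: 27 samples support only a few
bins, and 8 is a compromise between resolution and sampling noise. Patch
size, bin count and normalisation are all configurable; the defaults above
are the package's documented convention, not a claim about any external
implementation.

The sliding-window engine is vectorised over all voxels; a scalar
per-patch path exists independently and the two must agree to 1e-10 on
random volumes, which the suite checks for all five metrics.

## Feature extraction

Every (matrix, ROI) pair yields the same 105-feature vector: 14 shape
descriptors (mask-only), 18 first-order statistics, and 73 texture features
(22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM), following the IBSI-style
definitions used across radiomics toolkits. The usual GLCM set has 24
members; `SumAverage` (linearly redundant with `JointAverage` for symmetric
matrices) and `MCC` (unstable on small regions) are excluded so the
non-shape count is exactly 91. The shipped list is a versioned JSON
(`inst/extdata/feature_list_v1.json`). Shape uses voxel-face surface area
and PCA axis lengths (no mesh library is involved); the maximum-diameter
features reduce the surface voxels to per-slice convex-hull vertices before
the pairwise scan, which is exact for the farthest pair. Gray levels are
discretised with a fixed 25 HU
bin width for CT and a fixed 32-bin count for BED and the interaction
matrices, whose dynamic ranges differ by orders of magnitude. No wavelet or
LoG filtering is applied. GLCM and GLRLM are computed over the 13 unique
3-D directions and averaged; GLSZM zones use 26-connectivity.

With 4 ROIs and the model-specific matrix sets the table widths are
420 (CT), 420 (BED), 840 (CT+BED) and 2940 (composite, 7 matrices); these
identities are asserted on generated phantoms.

## Feature selection and classification

The cohort is split 84/16 stratified by failure (179 cases -> 151/28; the
training size is the ceiling of N x 0.84, allocated by largest remainder).
Importance is scored by repeated stratified 5-fold cross-validation (10
repeats by default; the repeat count is a convention, not published) over
four learners — RandomForest, ExtraTrees, AdaBoost (SAMME over depth-1
trees, implemented in-package), XGBoost — averaging each fit's native
importances after per-fit min-max normalisation. Raw averaging would let
the learner with the largest importance scale dominate; normalisation is a
deliberate soundness deviation and can be switched off. Ties break
lexicographically for determinism.

Redundancy filtering is a greedy scan in descending importance keeping a
feature only if its absolute training-set Pearson correlation with every
kept feature is at most 0.5, stopping at k = 17 (whether 17 was pre-chosen
or emergent is unknowable; it is a config default here).

The classifier is a Balanced Random Forest: each tree's bootstrap draws
minority-class-many cases from both classes. Grid search covers the
standard 2880-point grid (n_estimators, max_depth, min_samples_split,
min_samples_leaf, max_features, bootstrap, criterion) by 5-fold
cross-validated ROC-AUC. Two axes collapse operationally: `auto` equals
`sqrt` for classification, and none of the available tree learners exposes
an entropy split rule, so `entropy` rows are fitted with Gini and the model
records a note. The confusion threshold is 0.5 (unpublished; convention).

Evaluation: Mann-Whitney AUC (= trapezoidal ROC integration), accuracy,
sensitivity, specificity, Brier score, DeLong's paired AUC test
(placement-value covariance, two-sided, no multiplicity correction),
decision curves (net benefit vs treat-all/treat-none) and calibration
curves with ten equal-width bins.

## Competing-risk analysis

Treatment failure competes with death. The Fine-Gray subdistribution
hazard model is estimated in-package by an IPCW-weighted partial
likelihood: subjects with a competing event stay in later risk sets with
weight $G(t^-)/G(T_i^-)$ from the Kaplan-Meier censoring estimator; Newton
iterations run to a gradient max-norm below 1e-8 (cap 100, step halving).
Covariates are standardized internally and coefficients reported on the
original scale. The predicted cumulative incidence is
$1 - \exp(-\bar\Lambda(t)e^{x'\beta})$ with a Breslow-type baseline.
Discrimination uses a competing-risk-adapted concordance (pairs usable
when one case fails before the other's time or the other died of the
competing cause); calibration uses the IPCW Brier score and its
trapezoidal time-average (IBS). With no competing events and no censoring
the estimator reduces to Cox partial likelihood, checked numerically
against an established implementation; simulated subdistribution data with
$\beta = 0.7$ must be recovered within three standard errors.

## The phantom generator

Phantoms are parametric-geometric: correlated Gaussian noise lung
(~ -750 HU) with a spherical soft-tissue tumor (~ 0 HU), PTV = GTV dilated
5 mm, dose = prescription inside the PTV with exponential falloff (default
length 8 mm) and optional correlated multiplicative heterogeneity. They are
not anatomically realistic — no airways, vessels, breathing motion or
scanner kernel effects — so passing tests demonstrate pipeline correctness
and sensitivity, not clinical performance on real patients.

Cohorts jitter per-case geometry and plant outcome signal on a *measured*
feature: the mean Jensen-Shannon divergence in the peritumoral ring,
standardized across the cohort, enters a logistic model whose intercept is
calibrated so the expected failure fraction matches the target (default
54/179). Because the signal lives on an interaction matrix and the CT
jitter is independent of it, composite-model superiority over CT-only is a
designed, testable property. Default effect size is 2 log-odds per SD; the
end-to-end suite uses 3.5 ("strong signal"). Event times are exponential
(failure rate 1/18 per month; competing death 1/40 with probability 0.3
among non-failures; censoring 1/60) — magnitudes typical of SBRT follow-up.

## Problem sizes and numerical choices

The structural-count checks run three phantoms at 64 x 64 x 64 voxels; the
end-to-end experiments use 56-case cohorts of 24 x 24 x 14 phantoms
(1 x 1 x 2 mm), light shape+first-order extraction, importance ranking with
RandomForest and XGBoost at 2 repeats, k = 10, a single-point BRF grid and
a 70/30 split over ten seeds — sizes chosen so a full run completes on a
laptop core while leaving the planted effect clearly detectable. These are
the package's own scaled-down study conditions and are fixed in the
acceptance script.

Other conventions: alignment tolerance 1e-3 mm; inclusive thresholds at
both HU bounds and the 50% isodose; negative dose voxels clipped to zero
with a reported count; constant-patch conventions as above; NRRD round
trips are bit-exact (raw little-endian or full-precision ASCII).

## Known limitations

* Clinical AUC/Brier/c-index values from any real cohort are out of reach
  by design; the pipeline demonstrates *capability*, not clinical validity.
* The entropy split criterion of the BRF grid is fitted with Gini (no
  installed learner provides it); the grid interface is preserved and the
  substitution is recorded on the model object.
* DICOM import is not implemented; NRRD and NIfTI-1 are the supported
  containers.
* The exact pair of texture features excluded to reach 91 is a package
  convention; alternative choices are a one-line config change.
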
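# dosimix

Dosiomics for SBRT outcome modeling: voxel-level interaction of the
planning CT with the biologically effective dose (BED), standardized
radiomics feature extraction, and failure prediction with competing-risk
time-to-event analysis.

## The problem

Radiomics models of lung SBRT outcomes read only the CT; dose-volume
histograms read only the dose, and only marginally. The biology of
treatment failure plausibly depends on *where* dose lands in *which*
tissue. `dosimix` operationalises this by:

1. converting the plan's total physical dose to a voxelated BED under the
   linear-quadratic model,
   `BED = n d (1 + d / (α/β))`, with α/β = 10 Gy inside the PTV (tumor)
   and 3 Gy outside (normal tissue);
2. computing five CT-BED **interaction matrices** from paired 3×3×3
   patches at every voxel: joint entropy, Jensen-Shannon divergence,
   Wasserstein distance, Spearman rank correlation, and the pairwise
   product;
3. extracting a standardized 105-feature radiomics vector (14 shape + 18
   first-order + 73 texture) from four volumes of interest — the
   semi-automatic GTV (clinical GTV ∩ HU ∈ [-550, 2000]), the PTV, a 2 cm
   peritumoral ring, and ISO50 (≥ 50% of prescription outside the PTV) —
   on each matrix, giving model tables of 420 (CT), 420 (BED), 840
   (CT+BED) and 2940 (composite) features;
4. selecting features by repeated cross-validated importance (Random
   Forest, Extra Trees, AdaBoost, XGBoost) followed by a greedy Pearson
   redundancy filter (|r| ≤ 0.5, k = 17), and training a Balanced Random
   Forest with grid search;
5. evaluating with ROC/AUC, DeLong tests, decision curves, calibration and
   Brier scores, plus a self-contained Fine-Gray subdistribution-hazard
   model (c-index, time-dependent and integrated Brier score) for failure
   with death as a competing event.

A parametric phantom generator produces tumor-bearing CT cohorts with
SBRT-like dose falloff and outcome signal planted on an
interaction-matrix feature, so the entire pipeline is exercisable and
testable without patient data.

## Worked example

```r
library(dosimix)

# one synthetic case: 64^3 voxels at 1 x 1 x 2 mm, 50 Gy in 5 fractions
cs <- generate_phantom_case(phantom_spec(seed = 7))
cs
#> <study_case phantom: 64x64x64, 50 Gy in 5 fx, GTV 2128 vx, PTV 6832 vx>

bed <- compute_bed(cs$dose, cs$n_fractions, alpha_beta_map(cs$ptv))
range(bed$values[cs$ptv$values > 0])     # 10 Gy x 5 at alpha/beta 10
#> [1] 100 100

jsd <- interaction_volume(cs$ct, bed, "JSD")
ring <- peritumoral_ring(cs$ptv, 20)
mean(jsd$values[ring$values > 0])        # dissimilarity in the falloff shell
#> [1] 0.1506318

fv <- extract_features(jsd, ring)        # 105 standardized features
length(fv); fv["FirstOrder__Mean"]
#> [1] 105
#> FirstOrder__Mean
#>        0.1506318
```

The PTV interior receives exactly the prescription, so its BED is the
closed-form 100 Gy; the ring-averaged Jensen-Shannon divergence is the
kind of feature the cohort generator links to failure, and the 105-entry
vector is one (matrix, ROI) block of the model tables.

A full cohort run (generation, feature tables, selection, BRF, evaluation)
is one call:

```r
ch  <- generate_cohort(cohort_spec(n_cases = 56, shape = c(24, 24, 14),
                                   radius_range = c(4, 7), effect_size = 3.5,
                                   seed = 101))
# a single-point grid keeps this demo to about a minute; the default is
# the full 2880-configuration search
grid1 <- data.frame(n_estimators = 200L, max_depth = 5L,
                    min_samples_split = 2L, min_samples_leaf = 1L,
                    max_features = "sqrt", bootstrap = TRUE,
                    criterion = "gini", stringsAsFactors = FALSE)
res <- run_failure_pipeline(ch$cases, ch$outcomes,
                            model_kinds = c("CT", "COMPOSITE"),
                            classes = c("Shape", "FirstOrder"),
                            algorithms = c("RandomForest", "XGBoost"),
                            repeats = 2, k = 10, train_frac = 0.7,
                            grid = grid1, seed = 101)
res$CT$evaluation$auc; res$COMPOSITE$evaluation$auc
#> [1] 0.5818182
#> [1] 0.9272727
head(res$COMPOSITE$ranking$feature, 3)
#> [1] "JSD__RING__FirstOrder__Percentile90" "JSD__ISO50__FirstOrder__Mean"
#> [3] "JSD__RING__FirstOrder__InterquartileRange"
```

The planted JSD-ring signal is recovered at the top of the composite
ranking, and the composite model clearly beats the CT-only model on the
held-out cases — the qualitative behaviour the pipeline is designed to
expose.

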
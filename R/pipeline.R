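#' Preprocess a raw case onto the analysis grid
#'
#' Resamples CT/dose/masks to the analysis spacing (linear for volumes,
#' nearest for masks) and crops all matrices to the peritumoral envelope
#' (PTV plus ring) expanded by a margin, so that every per-case matrix
#' shares one grid.
#'
#' @param case a `study_case`.
#' @param spacing analysis voxel spacing (default 1 x 1 x 2 mm).
#' @param ring_mm peritumoral ring thickness used for the crop envelope.
#' @param margin_mm crop margin beyond the envelope (default 10 mm).
#' @return preprocessed `study_case`.
#' @export
preprocess_case <- function(case, spacing = c(1, 1, 2), ring_mm = 20,
                            margin_mm = 10) {
  cs <- resample_case(case, spacing)
  ring <- peritumoral_ring(cs$ptv, ring_mm)
  env <- as_roi_mask(cs$ptv,
                     pmax(cs$ptv$values, ring$values), label = "envelope")
  crop_bundle(cs, env, margin_mm)
}

#' Restrict a composite feature table to one model configuration
#'
#' Columns of a COMPOSITE table are prefixed by their source matrix, so
#' the CT-only, BED-only and CT+BED tables are column subsets.
#'
#' @param table a COMPOSITE `feature_table`.
#' @param model_kind target kind (`"CT"`, `"BED"`, `"CT_BED"`,
#'   `"COMPOSITE"`).
#' @return `feature_table` of the requested kind.
#' @export
subset_feature_table <- function(table, model_kind) {
  mats <- model_kind_matrices(model_kind)
  keep <- sub("__.*", "", colnames(table)) %in% mats
  structure(table[, keep, drop = FALSE], model_kind = model_kind,
            exclusions = attr(table, "exclusions"),
            class = class(table))
}

#' Run the failure-prediction pipeline on a cohort
#'
#' Full chain for one or more model configurations sharing a single
#' feature extraction and a single stratified split: build the composite
#' feature table, subset it per model kind, rank importance on the
#' training set, greedily select non-redundant features, tune a balanced
#' random forest, and evaluate on the held-out test set.
#'
#' @param cases list of preprocessed `study_case` objects.
#' @param outcomes outcomes data.frame (as [read_outcomes()]).
#' @param model_kinds model configurations to fit.
#' @param classes feature classes to extract (default all seven; a reduced
#'   set speeds up large simulated cohorts).
#' @param algorithms importance algorithms (see [rank_importance()]).
#' @param repeats importance CV repeats.
#' @param k number of selected features (default 17).
#' @param r_max redundancy threshold (default 0.5).
#' @param grid BRF hyperparameter grid (default [default_brf_grid()]).
#' @param train_frac training fraction (default 0.84).
#' @param seed master seed for split, ranking and tuning.
#' @return list with `split` and one entry per model kind containing
#'   `ranking`, `selected`, `model`, `evaluation`.
#' @export
run_failure_pipeline <- function(cases, outcomes,
                                 model_kinds = c("CT", "COMPOSITE"),
                                 classes = feature_classes,
                                 algorithms = c("RandomForest", "ExtraTrees",
                                                "AdaBoost", "XGBoost"),
                                 repeats = 10L, k = 17L, r_max = 0.5,
                                 grid = default_brf_grid(),
                                 train_frac = 0.84, seed = 1L) {
  comp <- build_feature_table(cases, "COMPOSITE", classes = classes)
  out <- list()
  sp_full <- split_train_test(comp, outcomes, train_frac = train_frac,
                              seed = seed)
  out$split <- list(train_ids = sp_full$train$ids, test_ids = sp_full$test$ids)
  for (mk in model_kinds) {
    tab <- subset_feature_table(comp, mk)
    trx <- tab[sp_full$train$ids, , drop = FALSE]
    tex <- tab[sp_full$test$ids, , drop = FALSE]
    # drop all-NA / zero-variance columns before ranking
    keep <- apply(trx, 2, function(v) sum(!is.na(v)) > 1 &&
                    stats::sd(v, na.rm = TRUE) > 0)
    trx <- trx[, keep, drop = FALSE]
    tex <- tex[, keep, drop = FALSE]
    rk <- rank_importance(trx, sp_full$train$y, algorithms = algorithms,
                          repeats = repeats, seed = seed)
    sel <- suppressWarnings(
      select_nonredundant(rk, trx, r_max = r_max, k = k))
    md <- tune_brf(trx, sp_full$train$y, sel, grid = grid, seed = seed)
    ev <- evaluate_classifier(md, tex[, md$features, drop = FALSE],
                              sp_full$test$y)
    out[[mk]] <- list(ranking = rk, selected = sel, model = md,
                      evaluation = ev)
  }
  out
}
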
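#' Stratified train/test split
#'
#' Splits a feature table into training and test sets stratified by the
#' failure label so both sets keep a similar failure rate. The training
#' set size is `ceiling(N * train_frac)` (84% of 179 cases gives the
#' 151/28 split), allocated across strata by largest remainder.
#'
#' @param table `feature_table` (rows named by case id).
#' @param outcomes data.frame with `case_id` and `failure` covering all rows.
#' @param train_frac training fraction (default 0.84).
#' @param seed RNG seed; the split is deterministic given it.
#' @return list with `train` and `test`, each a list `x` (feature matrix),
#'   `y` (integer 0/1 failure labels) and `ids`.
#' @export
split_train_test <- function(table, outcomes, train_frac = 0.84, seed = 1L) {
  ids <- rownames(table)
  m <- match(ids, outcomes$case_id)
  if (anyNA(m)) stop("outcomes do not cover all feature-table rows")
  y <- as.integer(outcomes$failure[m])
  strata <- split(seq_along(ids), y)
  if (any(lengths(strata) < 2L))
    stop("each outcome stratum needs at least 2 cases")
  N <- length(ids)
  n_train <- ceiling(N * train_frac)
  base <- vapply(strata, function(s) floor(length(s) * train_frac), numeric(1))
  rem <- vapply(strata, function(s) length(s) * train_frac, numeric(1)) - base
  extra <- n_train - sum(base)
  if (extra > 0) {
    ord <- order(-rem, -lengths(strata))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  tr <- with_seed(seed, {
    unlist(lapply(seq_along(strata), function(k) {
      s <- strata[[k]]
      sample(s, base[k])
    }))
  })
  tr <- sort(tr)
  te <- setdiff(seq_len(N), tr)
  list(train = list(x = table[tr, , drop = FALSE], y = y[tr], ids = ids[tr]),
       test = list(x = table[te, , drop = FALSE], y = y[te], ids = ids[te]))
}

# stratified fold assignment, both classes in every fold
make_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

minmax_scores <- function(v) {
  r <- range(v, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] == r[1]) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

ada_stump_importance <- function(X, y, n_rounds = 50L) {
  # SAMME AdaBoost over depth-1 rpart trees; importance is the
  # alpha-weighted sum of each stump's split improvement
  n <- nrow(X)
  w <- rep(1 / n, n)
  imp <- stats::setNames(numeric(ncol(X)), colnames(X))
  df <- data.frame(.y = factor(y), X, check.names = FALSE)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                       minsplit = 2, xval = 0,
                                                       maxsurrogate = 0,
                                                       maxcompete = 0))
    pred <- stats::predict(fit, type = "class")
    err <- sum(w * (pred != df$.y))
    if (is.na(err) || err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err)
    vi <- fit$variable.importance
    if (!is.null(vi)) {
      keep <- intersect(names(vi), names(imp))
      imp[keep] <- imp[keep] + alpha * vi[keep]
    }
    w <- w * exp(alpha * (pred != df$.y))
    w <- w / sum(w)
    if (err < 1e-8) break
  }
  imp
}

fit_importance_one <- function(algo, X, y, seed) {
  p <- ncol(X)
  imp <- switch(algo,
    RandomForest = {
      with_seed(seed, {
        rf <- randomForest::randomForest(x = X, y = factor(y), ntree = 100)
        rf$importance[, "MeanDecreaseGini"]
      })
    },
    ExtraTrees = {
      fit <- ranger::ranger(x = X, y = factor(y), num.trees = 100,
                            splitrule = "extratrees", importance = "impurity",
                            seed = seed, num.threads = 1)
      fit$variable.importance
    },
    AdaBoost = with_seed(seed, ada_stump_importance(X, y)),
    XGBoost = {
      bst <- with_seed(seed, xgboost::xgboost(
        x = X, y = factor(y, levels = c(0, 1)), nrounds = 50, max_depth = 3,
        learning_rate = 0.3, nthreads = 1, verbosity = 0, seed = seed))
      it <- xgboost::xgb.importance(model = bst)
      v <- stats::setNames(rep(0, p), colnames(X))
      v[it$Feature] <- it$Gain
      v
    },
    stop(sprintf("unknown importance algorithm '%s'", algo)))
  out <- stats::setNames(rep(0, p), colnames(X))
  out[names(imp)] <- imp
  out
}

#' Rank feature importance by repeated cross-validated ensembles
#'
#' Repeated stratified 5-fold cross-validation; in every (algorithm,
#' repeat, fold) combination the algorithm is fitted on the fold-training
#' part and its native per-feature importances are recorded, min-max
#' normalised to [0, 1] within the fit so that scores from heterogeneous
#' algorithms are commensurate before averaging (set
#' `normalize = FALSE` for raw-score averaging). The final score is the
#' mean over all fits; ties are broken lexicographically by feature id.
#'
#' @param train_x numeric feature matrix (training cases only).
#' @param labels 0/1 failure labels.
#' @param algorithms subset of RandomForest, ExtraTrees, AdaBoost, XGBoost.
#' @param folds CV folds (default 5).
#' @param repeats CV repeats (default 10).
#' @param seed RNG seed; the ranking is deterministic given it.
#' @param normalize per-fit min-max normalisation before averaging.
#' @return data.frame of class `importance_ranking` with columns `feature`
#'   and `score`, in descending score order.
#' @export
rank_importance <- function(train_x, labels,
                            algorithms = c("RandomForest", "ExtraTrees",
                                           "AdaBoost", "XGBoost"),
                            folds = 5L, repeats = 10L, seed = 1L,
                            normalize = TRUE) {
  if (length(unique(labels)) < 2L) stop("need both classes to rank features")
  X <- as.matrix(train_x)
  X[is.na(X)] <- 0   # constant/missing cells carry no ranking information
  acc <- stats::setNames(rep(0, ncol(X)), colnames(X))
  nfit <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- with_seed(seed + 1000L * r, make_folds(labels, folds))
    for (f in seq_len(folds)) {
      idx <- fold_id != f
      for (algo in algorithms) {
        s <- seed + 1000L * r + 10L * f + match(algo, algorithms)
        v <- fit_importance_one(algo, X[idx, , drop = FALSE], labels[idx], s)
        if (normalize) v <- minmax_scores(v)
        acc <- acc + v
        nfit <- nfit + 1L
      }
    }
  }
  score <- acc / nfit
  ord <- order(-score, names(score))
  structure(data.frame(feature = names(score)[ord], score = score[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("importance_ranking", "data.frame"))
}

#' Greedy non-redundant feature selection
#'
#' Scans features in descending importance; the top-ranked feature is kept
#' automatically, and each subsequent feature is kept only if its absolute
#' training-set Pearson correlation with every previously kept feature is
#' at most `r_max`. Stops once `k` features are kept.
#'
#' @param ranking an `importance_ranking` (or data.frame with `feature`).
#' @param train_x training feature matrix.
#' @param r_max redundancy threshold on |Pearson r| (default 0.5).
#' @param k target number of features (default 17). If fewer survive the
#'   filter, all survivors are returned with a warning.
#' @return character vector of selected feature ids (class
#'   `selected_feature_set`), in selection order.
#' @export
select_nonredundant <- function(ranking, train_x, r_max = 0.5, k = 17L) {
  feats <- ranking$feature
  if (!all(feats %in% colnames(train_x)))
    stop("ranking contains features absent from the table")
  X <- as.matrix(train_x)[, feats, drop = FALSE]
  kept <- character(0)
  for (f in feats) {
    if (length(kept) >= k) break
    ok <- TRUE
    for (g in kept) {
      r <- suppressWarnings(
        stats::cor(X[, f], X[, g], use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) > r_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, f)
  }
  if (length(kept) < k)
    warning(sprintf("only %d non-redundant features available (requested %d)",
                    length(kept), k))
  structure(kept, class = "selected_feature_set")
}
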
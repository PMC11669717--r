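make_table <- function(n, p, seed = 1, prefix = "f") {
  X <- dosimix:::with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  colnames(X) <- sprintf("%s%03d", prefix, seq_len(p))
  rownames(X) <- sprintf("case%03d", seq_len(n))
  X
}

outcomes_for <- function(X, y) {
  data.frame(case_id = rownames(X), failure = y,
             time_months = seq_len(nrow(X)), competing_death = 0)
}

test_that("a 179-case cohort splits into 151 train / 28 test, stratified", {
  X <- make_table(179, 3, seed = 2)
  y <- dosimix:::with_seed(3, as.integer(sample(rep(c(1, 0), c(54, 125)))))
  sp <- split_train_test(X, outcomes_for(X, y), train_frac = 0.84, seed = 9)
  expect_equal(nrow(sp$train$x), 151)
  expect_equal(nrow(sp$test$x), 28)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0)
  expect_equal(sort(c(sp$train$ids, sp$test$ids)), sort(rownames(X)))
  # stratification: train failure fraction within one case of the overall
  expect_lte(abs(mean(sp$train$y) - mean(y)), 1 / 151 + 1e-12)
  sp2 <- split_train_test(X, outcomes_for(X, y), train_frac = 0.84, seed = 9)
  expect_identical(sp$train$ids, sp2$train$ids)
  sp3 <- split_train_test(X, outcomes_for(X, y), train_frac = 0.84, seed = 10)
  expect_false(identical(sp$train$ids, sp3$train$ids))
  y1 <- c(1, rep(0, 178))
  expect_error(split_train_test(X, outcomes_for(X, y1)), "stratum")
})

test_that("a planted predictive feature outranks pure noise", {
  n <- 200
  X <- make_table(n, 21, seed = 5)
  y <- dosimix:::with_seed(6, as.integer(stats::runif(n) <
                                           stats::plogis(2.5 * X[, 7])))
  rk <- rank_importance(X, y, algorithms = c("RandomForest", "XGBoost"),
                        repeats = 2, seed = 11)
  expect_equal(rk$feature[1], "f007")
  expect_true(all(is.finite(rk$score)))
  # determinism
  rk2 <- rank_importance(X, y, algorithms = c("RandomForest", "XGBoost"),
                         repeats = 2, seed = 11)
  expect_identical(rk, rk2)
})

test_that("all four importance algorithms run and tolerate duplicate columns", {
  n <- 120
  X <- make_table(n, 8, seed = 7)
  X[, 8] <- X[, 1]          # duplicated predictor
  y <- dosimix:::with_seed(8, as.integer(stats::runif(n) <
                                           stats::plogis(2 * X[, 1])))
  rk <- rank_importance(X, y, repeats = 1, seed = 3)
  expect_setequal(rk$feature, colnames(X))
  expect_true(all(is.finite(rk$score)))
  expect_true(all(c("f001", "f008") %in% rk$feature[1:4]))
})

test_that("greedy redundancy filtering matches a brute-force reimplementation", {
  n <- 60
  X <- make_table(n, 30, seed = 12)
  # induce correlation blocks
  X[, 2] <- X[, 1] * 2
  X[, 3] <- X[, 1] + 0.1 * X[, 3]
  X[, 10] <- -X[, 4]
  ranking <- data.frame(feature = colnames(X),
                        score = seq(1, 0, length.out = 30))
  sel <- select_nonredundant(ranking, X, r_max = 0.5, k = 17)
  # independent oracle: literal greedy scan
  kept <- character(0)
  for (f in ranking$feature) {
    if (length(kept) >= 17) break
    cors <- if (length(kept)) abs(stats::cor(X[, f], X[, kept])) else 0
    if (all(cors <= 0.5)) kept <- c(kept, f)
  }
  expect_equal(as.character(sel), kept)
  # emitted set satisfies the pairwise constraint
  C <- abs(stats::cor(X[, as.character(sel)]))
  expect_true(all(C[upper.tri(C)] <= 0.5))
  expect_false("f002" %in% sel)   # exact linear copy of the top feature
})

test_that("uncorrelated features pass through by importance order and shortfalls warn", {
  X <- diag(10); colnames(X) <- sprintf("f%02d", 1:10)
  rownames(X) <- sprintf("c%02d", 1:10)
  ranking <- data.frame(feature = colnames(X), score = 10:1)
  X2 <- make_table(50, 10, seed = 14)
  sel <- select_nonredundant(data.frame(feature = colnames(X2),
                                        score = 10:1), X2, k = 5)
  expect_equal(as.character(sel), colnames(X2)[1:5])
  expect_warning(
    s2 <- select_nonredundant(data.frame(feature = colnames(X2), score = 10:1),
                              X2, k = 17),
    "non-redundant")
  expect_lte(length(s2), 17)
})

test_that("the default hyperparameter grid enumerates 2880 candidates", {
  g <- default_brf_grid()
  expect_equal(nrow(g), 4 * 4 * 5 * 3 * 3 * 2 * 2)
  expect_setequal(names(g), c("n_estimators", "max_depth", "min_samples_split",
                              "min_samples_leaf", "max_features", "bootstrap",
                              "criterion"))
})

test_that("grid search is deterministic and nails linearly separable data", {
  n <- 80
  X <- make_table(n, 5, seed = 21)
  y <- as.integer(X[, 1] > 0)
  g <- default_brf_grid()[c(1, 500, 1500, 2880), ]
  fit <- tune_brf(X, y, colnames(X), grid = g, seed = 4)
  fit2 <- tune_brf(X, y, colnames(X), grid = g, seed = 4)
  expect_identical(fit$best_params, fit2$best_params)
  tr_auc <- auc_mann_whitney(predict(fit, X), y)
  expect_gte(tr_auc, 0.99)
  pr <- predict(fit, X)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(predict(fit, X, type = "class") %in% 0:1))
})

test_that("single-class inputs are rejected", {
  X <- make_table(20, 3, seed = 22)
  expect_error(tune_brf(X, rep(1, 20), colnames(X)), "class")
  expect_error(rank_importance(X, rep(0, 20)), "class")
})
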
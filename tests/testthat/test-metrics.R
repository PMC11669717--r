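test_that("AUC equals brute-force concordant-pair counting on small examples", {
  y <- c(1, 0, 1, 0, 1, 0)
  s <- c(0.9, 0.2, 0.6, 0.55, 0.4, 0.1)
  brute <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  expect_equal(auc_mann_whitney(s, y), brute(s, y))
  # with ties
  s2 <- c(0.5, 0.5, 0.7, 0.2, 0.5, 0.7)
  expect_equal(auc_mann_whitney(s2, y), brute(s2, y))
  expect_equal(auc_mann_whitney(y, y), 1)
  ev <- evaluate_classifier(NULL, labels = y, probs = s)
  expect_equal(ev$auc, brute(s, y))
  expect_equal(ev$accuracy, mean((s >= 0.5) == y))
})

test_that("perfect and null classifiers bracket the AUC scale", {
  y <- rep(c(0, 1), 250)
  ev <- evaluate_classifier(NULL, labels = y, probs = y)
  expect_equal(ev$auc, 1); expect_equal(ev$accuracy, 1)
  expect_equal(ev$brier, 0)
  rnd <- dosimix:::with_seed(77, stats::runif(500))
  expect_lt(abs(auc_mann_whitney(rnd, y) - 0.5), 0.08)
  expect_warning(auc_mann_whitney(rnd, rep(1, 500)), "one class")
})

test_that("confusion-matrix identities hold at the probability threshold", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 1)
  p <- c(0.8, 0.3, 0.6, 0.1, 0.7, 0.2, 0.4, 0.9)
  ev <- evaluate_classifier(NULL, labels = y, probs = p)
  cm <- ev$confusion
  expect_equal(unname(cm["TP"] + cm["TN"] + cm["FP"] + cm["FN"]), 8)
  expect_equal(ev$accuracy, unname(cm["TP"] + cm["TN"]) / 8)
  expect_equal(ev$sensitivity, unname(cm["TP"] / (cm["TP"] + cm["FN"])))
  expect_equal(ev$specificity, unname(cm["TN"] / (cm["TN"] + cm["FP"])))
})

test_that("DeLong self-comparison gives p = 1 and agrees with evaluate()", {
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  a <- c(0.9, 0.6, 0.8, 0.4, 0.3, 0.5, 0.7, 0.1)
  d <- delong_test(a, a, y)
  expect_equal(d$p_value, 1)
  expect_equal(d$flag, "zero_variance")
  expect_equal(d$delta, 0)
  b <- c(0.2, 0.8, 0.7, 0.6, 0.4, 0.9, 0.5, 0.3)
  d2 <- delong_test(a, b, y)
  expect_equal(d2$auc_a, auc_mann_whitney(a, y))
  expect_equal(d2$auc_b, auc_mann_whitney(b, y))
  expect_true(d2$p_value > 0 && d2$p_value <= 1)
})

test_that("DeLong variance matches direct placement-value arithmetic", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 1)
  a <- c(0.81, 0.42, 0.65, 0.12, 0.55, 0.3, 0.2, 0.95)
  b <- c(0.5, 0.45, 0.7, 0.35, 0.6, 0.15, 0.4, 0.8)
  d <- delong_test(a, b, y)
  psi <- function(x, ys) mean((x > ys) + 0.5 * (x == ys))
  pos <- which(y == 1); neg <- which(y == 0)
  v10a <- sapply(pos, function(i) psi(a[i], a[neg]))
  v10b <- sapply(pos, function(i) psi(b[i], b[neg]))
  v01a <- sapply(neg, function(j) mean((a[pos] > a[j]) + 0.5 * (a[pos] == a[j])))
  v01b <- sapply(neg, function(j) mean((b[pos] > b[j]) + 0.5 * (b[pos] == b[j])))
  vd <- (stats::var(v10a) + stats::var(v10b) - 2 * stats::cov(v10a, v10b)) / 4 +
        (stats::var(v01a) + stats::var(v01b) - 2 * stats::cov(v01a, v01b)) / 4
  expect_equal(d$var, vd)
  expect_equal(d$delta, mean(v10a) - mean(v10b))
})

test_that("net benefit follows the decision-curve formula and its bounds", {
  y <- c(rep(1, 3), rep(0, 7))
  p <- c(0.9, 0.8, 0.3, 0.6, 0.4, 0.2, 0.1, 0.05, 0.3, 0.15)
  pts <- c(0.1, 0.25, 0.5)
  dc <- decision_curve(p, y, pts)
  for (i in seq_along(pts)) {
    pt <- pts[i]
    tp <- sum(p >= pt & y == 1); fp <- sum(p >= pt & y == 0)
    expect_equal(dc$net_benefit[i], tp / 10 - fp / 10 * pt / (1 - pt))
    expect_equal(dc$treat_all[i], 0.3 - 0.7 * pt / (1 - pt))
  }
  expect_true(all(dc$net_benefit <= mean(y) + 1e-12))
  expect_true(all(dc$treat_none == 0))
  # perfect classifier: NB equals prevalence below every positive's probability
  yp <- c(1, 1, 0, 0, 0)
  pp <- c(0.9, 0.85, 0.1, 0.2, 0.05)
  dcp <- decision_curve(pp, yp, c(0.3, 0.5, 0.8))
  expect_all_equal(dcp$net_benefit, mean(yp), tol = 1e-12)
  # thresholds at or above 1 are excluded
  expect_equal(nrow(decision_curve(p, y, c(0.5, 1, 1.5))), 1)
})

test_that("calibration bins and Brier scores match hand arithmetic", {
  y <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  expect_equal(calibration_curve(y, y)$brier, 0)
  expect_equal(calibration_curve(rep(0.5, 10), y)$brier, 0.25)
  p <- c(0.05, 0.12, 0.18, 0.33, 0.38, 0.52, 0.57, 0.74, 0.86, 0.95)
  cal <- calibration_curve(p, y, n_bins = 5)
  expect_equal(cal$curve$mean_predicted[1], mean(c(0.05, 0.12, 0.18)))
  expect_equal(cal$curve$observed_fraction[1], mean(c(1, 0, 1)))
  expect_equal(cal$curve$n, c(3, 2, 2, 1, 2))
  expect_equal(cal$brier, mean((p - y)^2))
  expect_error(calibration_curve(c(-0.1, 0.5), c(0, 1)), "0, 1")
})
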
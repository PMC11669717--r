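## Classifier evaluation: ROC/AUC, confusion metrics, DeLong's paired AUC
## test, decision-curve analysis, calibration and Brier score.

#' ROC AUC by the Mann-Whitney statistic
#'
#' Probability that a random failure case scores above a random
#' non-failure case, ties counted half -- identical to trapezoidal
#' integration of the empirical ROC curve.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1]; NA with a warning if only one class is present.
#' @export
auc_mann_whitney <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

roc_points <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1); N <- sum(labels == 0)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / P, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / N, numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Evaluate a failure classifier on held-out cases
#'
#' @param model a fitted classifier with a `predict(model, x)` method
#'   returning failure probabilities (e.g. `dosimix_brf`), or `NULL` if
#'   `probs` is given.
#' @param x test feature matrix (ignored when `probs` given).
#' @param labels 0/1 test labels.
#' @param threshold probability cut for the confusion matrix (default 0.5).
#' @param probs optional pre-computed probabilities.
#' @return list of class `model_evaluation`: `auc`, `accuracy`,
#'   `sensitivity`, `specificity`, `brier`, `confusion` (TP/FP/TN/FN),
#'   `roc` (curve points), `probs`.
#' @export
evaluate_classifier <- function(model, x = NULL, labels, threshold = 0.5,
                                probs = NULL) {
  if (is.null(probs)) probs <- predict(model, x)
  y <- as.integer(labels)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(list(
    auc = auc_mann_whitney(probs, y),
    accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    brier = mean((probs - y)^2),
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    roc = roc_points(probs, y),
    probs = probs, labels = y, threshold = threshold),
    class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("AUC %.3f | accuracy %.3f | sens %.3f | spec %.3f | Brier %.3f\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity, x$brier))
  invisible(x)
}

# placement values: for each positive, the fraction of negatives it beats
# (ties half), and vice versa
placement_values <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  v10 <- vapply(pos, function(s)
    mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s)
    mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated ROC AUCs
#'
#' Nonparametric comparison of the AUCs of two classifiers scored on the
#' same cases, using the covariance of their placement-value structural
#' components; two-sided p-value from the normal reference.
#'
#' @param scores_a,scores_b paired risk scores.
#' @param labels common 0/1 labels.
#' @return list: `auc_a`, `auc_b`, `delta`, `var`, `z`, `p_value`, `flag`
#'   (set when the difference has zero variance, e.g. self-comparison, in
#'   which case p = 1).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as.integer(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop("scores and labels must be paired")
  if (length(unique(y)) < 2L) stop("both classes required")
  pa <- placement_values(scores_a, y)
  pb <- placement_values(scores_b, y)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (!is.finite(vd) || vd <= 0) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, var = max(vd, 0),
                z = 0, p_value = 1, flag = "zero_variance"))
  }
  z <- delta / sqrt(vd)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, var = vd, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), flag = NULL)
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model's predicted failure probability at
#' each threshold probability pt:
#' `NB(pt) = TP/N - (FP/N) * pt/(1-pt)`,
#' against the treat-all reference `pi - (1-pi) * pt/(1-pt)` (prevalence
#' pi) and treat-none (0).
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels 0/1 labels.
#' @param thresholds grid of threshold probabilities in (0, 1); values
#'   >= 1 are dropped.
#' @return data.frame: `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(probs < 0 | probs > 1)) stop("`probs` must lie in [0, 1]")
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  y <- as.integer(labels)
  N <- length(y); prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    tp <- sum(probs >= pt & y == 1); fp <- sum(probs >= pt & y == 0)
    tp / N - fp / N * pt / (1 - pt)
  }, numeric(1))
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit = nb, treat_all = ta,
             treat_none = 0)
}

#' Calibration curve and Brier score
#'
#' Equal-width probability bins; empty bins are omitted. The Brier score
#' is the mean squared difference between predicted probability and
#' observed label.
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels 0/1 labels.
#' @param n_bins number of bins (default 10).
#' @return list: `curve` (data.frame `bin_mid`, `mean_predicted`,
#'   `observed_fraction`, `n`) and `brier`.
#' @export
calibration_curve <- function(probs, labels, n_bins = 10L) {
  if (any(probs < 0 | probs > 1)) stop("`probs` must lie in [0, 1]")
  y <- as.integer(labels)
  b <- pmin(floor(probs * n_bins) + 1L, n_bins)
  rows <- lapply(seq_len(n_bins), function(k) {
    i <- b == k
    if (!any(i)) return(NULL)
    data.frame(bin_mid = (k - 0.5) / n_bins,
               mean_predicted = mean(probs[i]),
               observed_fraction = mean(y[i]), n = sum(i))
  })
  list(curve = do.call(rbind, rows), brier = mean((probs - y)^2))
}
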
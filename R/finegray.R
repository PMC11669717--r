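## Fine-Gray subdistribution-hazard regression for treatment failure with
## death as a competing event. The estimator is authored here (IPCW-weighted
## partial likelihood with Kaplan-Meier censoring weights, Newton-Raphson)
## so the pipeline is self-contained; established survival packages serve
## as independent cross-checks in the test suite.

# Kaplan-Meier estimator of the censoring distribution; returns a function
# giving G(t-) (left limit) or G(t)
censor_km <- function(time, event) {
  ct <- sort(unique(time[event == 0]))
  surv <- numeric(length(ct))
  g <- 1
  for (i in seq_along(ct)) {
    s <- ct[i]
    g <- g * (1 - sum(time == s & event == 0) / sum(time >= s))
    surv[i] <- g
  }
  function(t, minus = TRUE) {
    vapply(t, function(tt) {
      idx <- if (minus) ct < tt else ct <= tt
      if (!any(idx)) 1 else surv[max(which(idx))]
    }, numeric(1))
  }
}

#' Fit a Fine-Gray subdistribution hazard model
#'
#' Maximizes the Fine-Gray weighted partial likelihood: subjects who
#' experience the competing event remain in later risk sets with
#' inverse-probability-of-censoring weights `G(t-)/G(T_i-)` from the
#' Kaplan-Meier estimator of the censoring distribution; Newton iterations
#' run until the gradient max-norm drops below `tol`. With no competing
#' events and no censoring the estimates coincide with an ordinary Cox
#' partial-likelihood fit.
#'
#' @param x covariate matrix (cases x covariates), e.g. the selected
#'   features.
#' @param time follow-up time (months).
#' @param event integer status: 0 censored, 1 failure, 2 competing death.
#' @param standardize centre/scale covariates before fitting (coefficients
#'   are reported on the original scale either way; default TRUE).
#' @param max_iter Newton iteration cap (default 100).
#' @param tol gradient max-norm convergence tolerance (default 1e-8).
#' @return object of class `fine_gray`: `coefficients`, `se`, `vcov`,
#'   `baseline` (step function data: `time`, `cumhaz`), `loglik`,
#'   `iterations`, `flags` (e.g. possible separation).
#' @export
fit_fine_gray <- function(x, time, event, standardize = TRUE,
                          max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  time <- as.numeric(time); event <- as.integer(event)
  n <- nrow(X); p <- ncol(X)
  if (!any(event == 1)) stop("no failure events in the data")
  if (!all(event %in% 0:2)) stop("event codes must be 0, 1 or 2")
  ctr <- rep(0, p); scl <- rep(1, p)
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  G <- censor_km(time, event)
  tf <- sort(unique(time[event == 1]))
  K <- length(tf)
  # IPCW risk-set weights, one row per failure time
  W <- matrix(0, K, n)
  Gt <- G(tf, minus = TRUE)
  Gi <- G(time, minus = TRUE)
  for (k in seq_len(K)) {
    at_risk <- time >= tf[k]
    W[k, at_risk] <- 1
    late <- time < tf[k] & event == 2
    W[k, late] <- Gt[k] / pmax(Gi[late], .Machine$double.eps)
  }
  Dk <- lapply(seq_len(K), function(k) which(time == tf[k] & event == 1))
  dk <- lengths(Dk)
  ll_grad_hess <- function(beta, want_hess = TRUE) {
    eta <- drop(Xs %*% beta)
    ex <- exp(eta)
    ll <- 0; gr <- rep(0, p)
    H <- if (want_hess) matrix(0, p, p) else NULL
    for (k in seq_len(K)) {
      w <- W[k, ] * ex
      S0 <- sum(w)
      S1 <- drop(crossprod(Xs, w))
      ll <- ll + sum(eta[Dk[[k]]]) - dk[k] * log(S0)
      mu <- S1 / S0
      gr <- gr + colSums(Xs[Dk[[k]], , drop = FALSE]) - dk[k] * mu
      if (want_hess) {
        S2 <- crossprod(Xs, Xs * w)
        H <- H + dk[k] * (S2 / S0 - tcrossprod(mu))
      }
    }
    list(ll = ll, gr = gr, H = H)
  }
  beta <- rep(0, p)
  cur <- ll_grad_hess(beta)
  iter <- 0L
  flags <- character(0)
  repeat {
    if (max(abs(cur$gr)) < tol) break
    iter <- iter + 1L
    if (iter > max_iter)
      stop(sprintf(
        "Fine-Gray Newton did not converge in %d iterations (|grad| = %.3g)",
        max_iter, max(abs(cur$gr))))
    step <- tryCatch(solve(cur$H, cur$gr),
                     error = function(e) cur$gr / max(diag(cur$H), 1e-8))
    s <- 1
    repeat {
      cand <- beta + s * step
      nxt <- ll_grad_hess(cand)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) break
      s <- s / 2
      if (s < 1e-8) break
    }
    beta <- beta + s * step
    cur <- nxt
  }
  if (max(abs(beta)) > 50)
    flags <- c(flags, "possible complete separation (|beta| > 50)")
  vc_std <- tryCatch(solve(cur$H), error = function(e) matrix(NA, p, p))
  # back-transform to the original covariate scale
  beta_o <- beta / scl
  vc_o <- vc_std / tcrossprod(scl)
  eta0 <- sum(ctr * beta_o)
  ex <- exp(drop(Xs %*% beta))
  h0 <- vapply(seq_len(K), function(k) dk[k] / sum(W[k, ] * ex), numeric(1))
  baseline <- data.frame(time = tf, cumhaz = cumsum(h0) * exp(-eta0))
  structure(list(coefficients = stats::setNames(beta_o, colnames(X)),
                 se = stats::setNames(sqrt(diag(vc_o)), colnames(X)),
                 vcov = vc_o, baseline = baseline, loglik = cur$ll,
                 iterations = iter, flags = flags, n = n,
                 n_events = sum(event == 1), center = ctr, scale = scl,
                 time_range = range(time)),
            class = "fine_gray")
}

#' @export
coef.fine_gray <- function(object, ...) object$coefficients

#' @export
print.fine_gray <- function(x, ...) {
  cat(sprintf("Fine-Gray subdistribution hazard model (%d cases, %d failures)\n",
              x$n, x$n_events))
  print(round(x$coefficients, 4))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.fine_gray <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(coef = object$coefficients, se = object$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik,
                 iterations = object$iterations, flags = object$flags),
            class = "summary.fine_gray")
}

#' @export
print.summary.fine_gray <- function(x, ...) {
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Predicted cumulative incidence of failure
#'
#' `CIF(t | x) = 1 - exp(-Lambda0(t) * exp(x'beta))`: non-decreasing in t,
#' bounded in [0, 1], ordered across covariate profiles by their linear
#' predictor. Beyond the last observed failure time the curve is held
#' constant and the result carries an `extrapolated` attribute.
#'
#' @param fit a `fine_gray` model.
#' @param newx covariate matrix (original scale).
#' @param times evaluation times.
#' @return matrix (rows = cases, columns = times) of CIF values.
#' @export
cumulative_incidence <- function(fit, newx, times) {
  stopifnot(inherits(fit, "fine_gray"))
  newx <- as.matrix(newx)
  lp <- drop(newx %*% fit$coefficients)
  bl <- fit$baseline
  idx <- findInterval(times, bl$time)
  ch <- c(0, bl$cumhaz)[idx + 1]
  out <- 1 - exp(-outer(exp(lp), ch))
  dimnames(out) <- list(rownames(newx), NULL)
  if (any(times > max(bl$time))) attr(out, "extrapolated") <- TRUE
  out
}

#' @export
predict.fine_gray <- function(object, newx, times = NULL,
                              type = c("lp", "cif"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (type == "lp") return(drop(newx %*% object$coefficients))
  if (is.null(times)) times <- object$baseline$time
  cumulative_incidence(object, newx, times)
}

#' Competing-risk concordance index
#'
#' Fraction of usable case pairs ordered correctly by predicted risk. A
#' pair (i, j) is usable when i fails and either j's observed time exceeds
#' i's or j experienced the competing event (so j is known not to fail);
#' concordance means the failing-earlier case has the higher risk score
#' (ties count half).
#'
#' @param risk numeric risk scores (higher = earlier failure expected),
#'   e.g. the Fine-Gray linear predictor.
#' @param time follow-up times.
#' @param event status 0/1/2 as in [fit_fine_gray()].
#' @return c-index in [0, 1]; NA with a warning when no usable pairs exist.
#' @export
concordance_index <- function(risk, time, event) {
  event <- as.integer(event)
  num <- 0; den <- 0
  for (i in which(event == 1)) {
    comp <- which(time > time[i] | (event == 2 & time <= time[i]))
    comp <- comp[comp != i]
    if (!length(comp)) next
    den <- den + length(comp)
    num <- num + sum(risk[i] > risk[comp]) + 0.5 * sum(risk[i] == risk[comp])
  }
  if (den == 0) {
    warning("no usable pairs for the concordance index")
    return(NA_real_)
  }
  num / den
}

#' Time-dependent Brier score and integrated Brier score
#'
#' IPCW Brier score comparing predicted cumulative incidence at each time
#' to the observed failure status (Graf weights from the censoring
#' Kaplan-Meier estimator; with no censoring all weights are 1 and the
#' score is a plain mean squared error). Times where the censoring
#' survivor function vanishes are excluded and flagged.
#'
#' @param fit a `fine_gray` model.
#' @param newx covariate matrix.
#' @param time,event observed outcomes for the evaluated cases.
#' @param times evaluation time grid.
#' @return data.frame `time`, `brier` (class `brier_curve`), possibly with
#'   attribute `excluded` listing dropped times.
#' @export
brier_curve <- function(fit, newx, time, event, times) {
  cif <- cumulative_incidence(fit, newx, times)
  G <- censor_km(time, event)
  Gi <- G(time, minus = TRUE)
  out <- numeric(length(times))
  keep <- logical(length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    Gt <- G(t, minus = FALSE)
    w <- numeric(length(time))
    past <- time <= t & event != 0
    fut <- time > t
    if ((any(past) && any(Gi[past] <= 0)) || (any(fut) && Gt <= 0)) {
      keep[k] <- FALSE
      next
    }
    w[past] <- 1 / Gi[past]
    w[fut] <- 1 / Gt
    ind <- as.numeric(time <= t & event == 1)
    out[k] <- mean(w * (ind - cif[, k])^2)
    keep[k] <- TRUE
  }
  res <- data.frame(time = times[keep], brier = out[keep])
  class(res) <- c("brier_curve", "data.frame")
  if (any(!keep)) attr(res, "excluded") <- times[!keep]
  res
}

#' Integrated Brier score by trapezoidal integration
#' @param curve a `brier_curve` (data.frame `time`, `brier`).
#' @return time-averaged Brier score over the curve's range.
#' @export
integrated_brier <- function(curve) {
  t <- curve$time; b <- curve$brier
  if (length(t) < 2L) return(mean(b))
  sum(diff(t) * (utils::head(b, -1) + utils::tail(b, -1)) / 2) /
    (max(t) - min(t))
}

#' Simulate a cohort from a Fine-Gray generative model
#'
#' Standard subdistribution simulation: with covariate effect `beta`, the
#' failure CIF is `F1(t|x) = 1 - [1 - p_mix (1 - e^{-t})]^{exp(x'beta)}`,
#' competing-event times are exponential for the remaining mass, and
#' censoring is independent exponential. Used for parameter-recovery and
#' null checks.
#'
#' @param n cases.
#' @param beta covariate effect(s); covariates are iid standard normal.
#' @param p_mix baseline failure mass (default 0.6).
#' @param event2_rate exponential rate of competing-event times.
#' @param cens_rate censoring rate (0 = no censoring).
#' @param seed RNG seed.
#' @return list `x` (matrix), `time`, `event` (0/1/2).
#' @export
simulate_crisk_cohort <- function(n, beta, p_mix = 0.6, event2_rate = 0.5,
                                  cens_rate = 0, seed = 1L) {
  beta <- as.numeric(beta)
  p <- length(beta)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    eta <- exp(drop(X %*% beta))
    P1 <- 1 - (1 - p_mix)^eta
    is1 <- stats::rbinom(n, 1, P1) == 1
    U <- stats::runif(n)
    t1 <- -log(1 - (1 - (1 - U * P1)^(1 / eta)) / p_mix)
    t2 <- stats::rexp(n, event2_rate)
    tev <- ifelse(is1, t1, t2)
    ev <- ifelse(is1, 1L, 2L)
    if (cens_rate > 0) {
      cc <- stats::rexp(n, cens_rate)
      ev[cc < tev] <- 0L
      tev <- pmin(tev, cc)
    }
    list(x = X, time = tev, event = ev)
  })
}
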
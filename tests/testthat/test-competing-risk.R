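test_that("with no competing events or censoring the fit reduces to Cox", {
  sim <- simulate_crisk_cohort(150, c(0.8, -0.4), p_mix = 0.999999, seed = 2)
  keep <- sim$event == 1
  fg <- fit_fine_gray(sim$x[keep, ], sim$time[keep], sim$event[keep])
  cx <- survival::coxph(
    survival::Surv(sim$time[keep], rep(1, sum(keep))) ~ sim$x[keep, ],
    ties = "breslow")
  expect_equal(unname(coef(fg)), unname(coef(cx)), tolerance = 1e-6)
})

test_that("a covariate unrelated to the outcome gets a near-zero coefficient", {
  sim <- simulate_crisk_cohort(400, 0.5, cens_rate = 0.1, seed = 31)
  xnull <- dosimix:::with_seed(32, matrix(stats::rnorm(400), ncol = 1))
  fg <- fit_fine_gray(xnull, sim$time, sim$event)
  expect_lt(abs(coef(fg) / fg$se), 2)
})

test_that("the subdistribution effect beta = 0.7 is recovered on simulated data", {
  sim <- simulate_crisk_cohort(500, 0.7, cens_rate = 0.1, seed = 5)
  fg <- fit_fine_gray(matrix(sim$x, ncol = 1), sim$time, sim$event)
  expect_lt(abs(unname(coef(fg)) - 0.7), 3 * fg$se)
  expect_equal(length(fg$flags), 0)
  expect_true(all(diff(fg$baseline$cumhaz) >= 0))
})

test_that("the estimator agrees with an established competing-risk fit", {
  sim <- simulate_crisk_cohort(300, c(0.6, -0.3), cens_rate = 0.15, seed = 8)
  fg <- fit_fine_gray(sim$x, sim$time, sim$event)
  cr <- cmprsk::crr(sim$time, sim$event, sim$x)
  expect_equal(unname(coef(fg)), unname(cr$coef), tolerance = 1e-4)
})

test_that("cumulative incidence is zero at t = 0, monotone, bounded and ordered", {
  sim <- simulate_crisk_cohort(250, 0.8, cens_rate = 0.1, seed = 13)
  fg <- fit_fine_gray(matrix(sim$x, ncol = 1), sim$time, sim$event)
  newx <- matrix(c(-2, 0, 2), ncol = 1)
  times <- c(0, sort(dosimix:::with_seed(14, stats::runif(20, 0, max(sim$time)))))
  cif <- cumulative_incidence(fg, newx, times)
  expect_all_equal(cif[, 1], 0, tol = 1e-12)
  expect_true(all(cif >= 0 & cif <= 1))
  expect_true(all(apply(cif, 1, function(r) all(diff(r) >= -1e-12))))
  # profiles ordered by linear predictor at every time
  expect_true(all(cif[1, ] <= cif[2, ] + 1e-12))
  expect_true(all(cif[2, ] <= cif[3, ] + 1e-12))
  # extrapolation beyond follow-up is held constant and flagged
  cif2 <- cumulative_incidence(fg, newx, c(max(sim$time) * 2))
  expect_true(isTRUE(attr(cif2, "extrapolated")))
  expect_equal(unname(cif2[, 1]),
               unname(cumulative_incidence(fg, newx, max(fg$baseline$time))[, 1]))
})

test_that("the concordance index matches exhaustive pair enumeration", {
  # perfect ordering
  tt <- c(2, 5, 9, 13, 20)
  expect_equal(concordance_index(-tt, tt, rep(1, 5)), 1)
  # 5-case hand example with competing events and censoring
  time <- c(3, 6, 4, 8, 2)
  event <- c(1, 0, 2, 1, 2)
  risk <- c(0.9, 0.1, 0.5, 0.7, 0.3)
  num <- den <- 0
  for (i in 1:5) {
    if (event[i] != 1) next
    for (j in setdiff(1:5, i)) {
      if (time[j] > time[i] || event[j] == 2) {
        den <- den + 1
        num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
      }
    }
  }
  expect_equal(concordance_index(risk, time, event), num / den)
  # random scores hover near 1/2
  n <- 600
  tm <- dosimix:::with_seed(15, stats::rexp(n))
  rs <- dosimix:::with_seed(16, stats::rnorm(n))
  expect_lt(abs(concordance_index(rs, tm, rep(1, n)) - 0.5), 0.06)
  expect_warning(concordance_index(1, 5, 0), "no usable pairs")
})

test_that("Brier curves reduce to plain MSE without censoring and integrate by trapezoid", {
  sim <- simulate_crisk_cohort(200, 0.7, cens_rate = 0, seed = 18)
  fg <- fit_fine_gray(matrix(sim$x, ncol = 1), sim$time, sim$event)
  times <- stats::quantile(sim$time, c(0.2, 0.4, 0.6), names = FALSE)
  bc <- brier_curve(fg, matrix(sim$x, ncol = 1), sim$time, sim$event, times)
  cif <- cumulative_incidence(fg, matrix(sim$x, ncol = 1), times)
  for (k in seq_along(times)) {
    ind <- as.numeric(sim$time <= times[k] & sim$event == 1)
    expect_equal(bc$brier[k], mean((ind - cif[, k])^2))
  }
  ibs <- integrated_brier(bc)
  t <- bc$time; b <- bc$brier
  expect_equal(ibs, sum(diff(t) * (head(b, -1) + tail(b, -1)) / 2) /
                 (max(t) - min(t)))
})

test_that("a 0.5-constant prediction scores Brier 0.25 on balanced uncensored outcomes", {
  # direct check of the scoring rule at one time with balanced status
  n <- 40
  time <- c(rep(1, 20), rep(10, 20))   # 20 early failures, 20 late
  event <- c(rep(1, 20), rep(1, 20))
  sim_fit <- fit_fine_gray(matrix(stats::rnorm(n), ncol = 1), time, event)
  fake <- sim_fit
  # force a flat 0.5 CIF prediction via a zero coefficient and fixed baseline
  fake$coefficients[] <- 0
  fake$baseline <- data.frame(time = 0.5, cumhaz = log(2))  # CIF = 0.5 for t >= 0.5
  bc <- brier_curve(fake, matrix(0, n, 1), time, event, times = 5)
  expect_equal(bc$brier, 0.25)
})

test_that("parameter recovery stays within 10% bias at n = 1000", {
  sim <- simulate_crisk_cohort(1000, 0.7, cens_rate = 0.1, seed = 23)
  fg <- fit_fine_gray(matrix(sim$x, ncol = 1), sim$time, sim$event)
  expect_lt(abs(unname(coef(fg)) - 0.7) / 0.7, 0.10)
})
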
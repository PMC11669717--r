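## Synthetic tumor-bearing CT phantoms with SBRT-like dose falloff.
##
## The phantom is parametric-geometric, not anatomically realistic: a noisy
## lung background around -750 HU, a spherical soft-tissue tumor near 0 HU
## with spatially correlated texture, a PTV obtained by 5 mm isotropic
## dilation of the GTV, and a dose that equals the prescription inside the
## PTV and decays exponentially with physical distance outside it. This is
## sufficient to exercise HU thresholds, ring/isodose construction, the LQ
## BED transform, patch metrics, feature counts and the modeling stack
## without patient data.

# evaluate `code` under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

arr_shift_clamp <- function(A, off) {
  d <- dim(A)
  A[clamp_idx(seq_len(d[1]) + off[1], d[1]),
    clamp_idx(seq_len(d[2]) + off[2], d[2]),
    clamp_idx(seq_len(d[3]) + off[3], d[3]), drop = FALSE]
}

# cheap separable box smoothing for correlated noise texture
box_smooth <- function(A, passes = 2L) {
  for (p in seq_len(passes)) for (a in 1:3) {
    up <- ifelse(1:3 == a, 1, 0); dn <- -up
    A <- (A + arr_shift_clamp(A, up) + arr_shift_clamp(A, dn)) / 3
  }
  A
}

#' Specification of one synthetic phantom case
#'
#' @param shape voxel grid dimensions (default 64 x 64 x 64).
#' @param spacing mm per axis (default 1 x 1 x 2).
#' @param tumor_center_mm physical tumor centre; default volume centre.
#' @param tumor_radius_mm tumor radius (mm).
#' @param tumor_hu_mean,tumor_hu_sd tumor HU distribution (soft tissue).
#' @param lung_hu_mean,lung_hu_sd background HU distribution.
#' @param texture_passes smoothing passes for the correlated noise texture.
#' @param prescription_gy prescription dose (default 50 Gy, the dominant
#'   10 Gy x 5 SBRT scheme).
#' @param n_fractions fraction count (default 5).
#' @param falloff_mm exponential dose falloff length outside the PTV.
#' @param ptv_margin_mm GTV-to-PTV dilation margin (default 5 mm).
#' @param dose_noise_sd relative amplitude of multiplicative correlated
#'   dose heterogeneity (0 = smooth falloff only).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 2),
                         tumor_center_mm = NULL, tumor_radius_mm = 10,
                         tumor_hu_mean = 0, tumor_hu_sd = 30,
                         lung_hu_mean = -750, lung_hu_sd = 60,
                         texture_passes = 2L,
                         prescription_gy = 50, n_fractions = 5L,
                         falloff_mm = 8, ptv_margin_mm = 5,
                         dose_noise_sd = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(tumor_center_mm)) tumor_center_mm <- (shape - 1) * spacing / 2
  ext <- (shape - 1) * spacing
  if (falloff_mm <= 0) stop("`falloff_mm` must be positive")
  if (any(tumor_center_mm - tumor_radius_mm < 0) ||
      any(tumor_center_mm + tumor_radius_mm > ext))
    stop("tumor sphere does not fit inside the volume")
  structure(as.list(environment()), class = "phantom_spec")
}

#' Generate one synthetic study case
#'
#' @param spec a [phantom_spec()].
#' @param case_id identifier for the generated case.
#' @return a `study_case` (outcome NULL; see [generate_cohort()]).
#' @export
generate_phantom_case <- function(spec, case_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$shape; sp <- spec$spacing
    ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
    # squared distance to tumor centre, mm
    r2 <- outer(outer((ax[[1]] - spec$tumor_center_mm[1])^2,
                      (ax[[2]] - spec$tumor_center_mm[2])^2, "+"),
                (ax[[3]] - spec$tumor_center_mm[3])^2, "+")
    gtv <- array(as.numeric(r2 <= spec$tumor_radius_mm^2), d)
    noise <- box_smooth(array(stats::rnorm(prod(d)), d), spec$texture_passes)
    noise <- noise / stats::sd(noise)
    ct <- spec$lung_hu_mean + spec$lung_hu_sd * noise
    ct[gtv > 0] <- spec$tumor_hu_mean + spec$tumor_hu_sd * noise[gtv > 0]
    gtv_mask <- roi_mask(gtv, sp, label = "GTV")
    dist_gtv <- distance_map_mm(gtv_mask)
    ptv <- array(as.numeric(dist_gtv <= spec$ptv_margin_mm), d)
    ptv_mask <- roi_mask(ptv, sp, label = "PTV")
    dist_ptv <- distance_map_mm(ptv_mask)
    dose <- spec$prescription_gy * exp(-dist_ptv / spec$falloff_mm)
    if (spec$dose_noise_sd > 0) {
      dn <- box_smooth(array(stats::rnorm(prod(d)), d), spec$texture_passes)
      dn <- dn / stats::sd(dn)
      dose <- pmax(dose * (1 + spec$dose_noise_sd * dn), 0)
    }
    study_case(case_id,
               ct = volume_grid(ct, sp),
               dose = volume_grid(array(dose, d), sp),
               clinical_gtv = gtv_mask, ptv = ptv_mask,
               prescription_dose = spec$prescription_gy,
               n_fractions = spec$n_fractions)
  })
}

#' Specification of a synthetic cohort
#'
#' Per-case phantom parameters are jittered; the failure label is drawn
#' from a logistic model on a designated measurable feature (by default the
#' mean Jensen-Shannon divergence in the peritumoral ring), standardized
#' across the cohort, with the intercept calibrated so the expected failure
#' fraction matches `failure_fraction`. Planting the signal on an
#' interaction-matrix feature makes superiority of the composite model over
#' the CT-only model a testable property of the pipeline. Event times are
#' exponential conditional on the label; non-failing cases die of the
#' competing cause with probability `death_prob`, otherwise they are
#' censored.
#'
#' @param n_cases cohort size (default 179).
#' @param failure_fraction expected failure rate (default 54/179).
#' @param effect_size log-odds of failure per SD of the signal feature
#'   (default 2; 0 gives a null cohort).
#' @param signal one of `"jsd_ring_mean"` (default) or `"none"` (labels
#'   drawn iid at `failure_fraction`, no volumes-based signal; also skips
#'   the interaction computation, useful for fast split/size checks).
#' @param shape,spacing phantom grid (cohort default 32 x 32 x 20 at
#'   1 x 1 x 2 mm; smaller than the single-phantom default to keep
#'   cohort-scale runs tractable).
#' @param radius_range per-case tumor radius jitter (mm, uniform); must fit
#'   inside `shape` with room for the PTV margin.
#' @param rate_failure,rate_death,rate_censor exponential rates per month
#'   for failure times, competing-death times and censoring times.
#' @param death_prob probability that a non-failing case dies of the
#'   competing cause.
#' @param n_bins interaction histogram bins for the signal feature.
#' @param seed master seed; per-case seeds are derived from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 179L, failure_fraction = 54 / 179,
                        effect_size = 2, signal = c("jsd_ring_mean", "none"),
                        shape = c(32, 32, 20), spacing = c(1, 1, 2),
                        radius_range = c(6, 11),
                        rate_failure = 1 / 18, rate_death = 1 / 40,
                        rate_censor = 1 / 60, death_prob = 0.3,
                        n_bins = 8L, seed = 1L) {
  signal <- match.arg(signal)
  if (failure_fraction <= 0 || failure_fraction >= 1)
    stop("`failure_fraction` must be in (0,1)")
  if (min(rate_failure, rate_death, rate_censor) <= 0)
    stop("event rates must be positive")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort with planted outcome signal
#'
#' @param spec a [cohort_spec()].
#' @return list with `cases` (list of `study_case`, outcomes attached),
#'   `outcomes` (data.frame as [read_outcomes()]), `signal_value` (the
#'   per-case true feature driving failure, NA for signal `"none"`) and
#'   `failure_prob` (the per-case generative probabilities).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cases
    case_seeds <- sample.int(2^30, n)
    jit <- data.frame(
      radius = stats::runif(n, spec$radius_range[1], spec$radius_range[2]),
      falloff = stats::runif(n, 5, 12),
      dose_noise = stats::runif(n, 0.02, 0.30),
      tumor_hu = stats::rnorm(n, 0, 20),
      lung_hu = stats::rnorm(n, -750, 25))
    cases <- vector("list", n)
    sig <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ps <- phantom_spec(shape = spec$shape, spacing = spec$spacing,
                         tumor_radius_mm = jit$radius[i],
                         tumor_hu_mean = jit$tumor_hu[i],
                         lung_hu_mean = jit$lung_hu[i],
                         falloff_mm = jit$falloff[i],
                         dose_noise_sd = jit$dose_noise[i],
                         seed = case_seeds[i])
      cs <- generate_phantom_case(ps, case_id = sprintf("case%04d", i))
      if (spec$signal == "jsd_ring_mean") {
        bed <- compute_bed(cs$dose, cs$n_fractions, alpha_beta_map(cs$ptv))
        jsd <- interaction_volume(cs$ct, bed, "JSD", n_bins = spec$n_bins)
        ring <- peritumoral_ring(cs$ptv, 20)
        sig[i] <- mean(jsd$values[ring$values > 0])
      }
      cases[[i]] <- cs
    }
    if (spec$signal == "none" || spec$effect_size == 0) {
      p <- rep(spec$failure_fraction, n)
    } else {
      z <- as.numeric(scale(sig))
      # calibrate the intercept so mean failure probability hits the target
      a <- stats::uniroot(function(a0)
        mean(stats::plogis(a0 + spec$effect_size * z)) - spec$failure_fraction,
        c(-30, 30))$root
      p <- stats::plogis(a + spec$effect_size * z)
    }
    failure <- stats::rbinom(n, 1, p)
    t_fail <- stats::rexp(n, spec$rate_failure)
    t_death <- stats::rexp(n, spec$rate_death)
    t_cens <- stats::rexp(n, spec$rate_censor)
    dies <- stats::rbinom(n, 1, spec$death_prob)
    time <- ifelse(failure == 1, t_fail, ifelse(dies == 1, t_death, t_cens))
    death <- as.integer(failure == 0 & dies == 1)
    for (i in seq_len(n))
      cases[[i]]$outcome <- outcome_record(failure[i] == 1, time[i],
                                           death[i] == 1)
    outcomes <- data.frame(
      case_id = vapply(cases, function(cs) cs$case_id, character(1)),
      failure = failure, time_months = time, competing_death = death,
      stringsAsFactors = FALSE)
    list(cases = cases, outcomes = outcomes, signal_value = sig,
         failure_prob = p)
  })
}
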
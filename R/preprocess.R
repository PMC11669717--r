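#' Resample a volume to a new voxel spacing
#'
#' Resamples onto a grid with the requested spacing that preserves the
#' physical extent of the input within one voxel (new axis length
#' `round(n * old / new)`), sampling at physical positions measured from the
#' same origin. CT, dose and interaction volumes use trilinear interpolation;
#' masks must use nearest-neighbour so the output stays binary. The default
#' analysis grid is 1 x 1 x 2 mm.
#'
#' @param vol a `volume_grid` or `roi_mask`.
#' @param target_spacing numeric length-3, mm per axis.
#' @param mode `"linear"` (trilinear) or `"nearest"`.
#' @return resampled object of the same class.
#' @export
resample <- function(vol, target_spacing, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "volume_grid"))
  ts <- as.numeric(target_spacing)
  if (length(ts) != 3L || any(!is.finite(ts)) || any(ts <= 0))
    stop("`target_spacing` must be three strictly positive numbers (mm)")
  if (inherits(vol, "roi_mask") && mode != "nearest")
    stop("masks must be resampled with mode = \"nearest\"")
  d <- dim(vol$values); sp <- vol$spacing
  nd <- pmax(1L, as.integer(round(d * sp / ts)))
  frac <- lapply(1:3, function(a) {
    f <- (seq_len(nd[a]) - 1) * ts[a] / sp[a]   # 0-based source index
    pmin(pmax(f, 0), d[a] - 1)
  })
  A <- vol$values
  if (mode == "nearest") {
    idx <- lapply(1:3, function(a) as.integer(round(frac[[a]])) + 1L)
    A <- A[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    for (a in 1:3) A <- interp_axis(A, a, frac[[a]])
  }
  dim(A) <- nd
  if (inherits(vol, "roi_mask"))
    roi_mask(A, spacing = ts, origin = vol$origin, direction = vol$direction,
             label = vol$label)
  else
    volume_grid(A, spacing = ts, origin = vol$origin, direction = vol$direction)
}

# linear interpolation along one array axis at 0-based fractional indices f
interp_axis <- function(A, axis, f) {
  d <- dim(A); n <- d[axis]
  lo <- pmin(pmax(floor(f), 0), n - 1)
  hi <- pmin(lo + 1, n - 1)
  w <- f - lo
  idx <- lapply(d, seq_len)
  idx_lo <- idx; idx_lo[[axis]] <- lo + 1
  idx_hi <- idx; idx_hi[[axis]] <- hi + 1
  Al <- do.call(`[`, c(list(A), idx_lo, list(drop = FALSE)))
  Ah <- do.call(`[`, c(list(A), idx_hi, list(drop = FALSE)))
  if (all(w == 0)) return(Al)
  wi <- w[slice.index(Al, axis)]
  Al * (1 - wi) + Ah * wi
}

crop_indices <- function(mask_values, spacing, margin_mm) {
  pos <- which(mask_values > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop("crop envelope is empty")
  d <- dim(mask_values)
  pad <- ceiling(margin_mm / spacing)
  lo <- pmax(apply(pos, 2, min) - pad, 1)
  hi <- pmin(apply(pos, 2, max) + pad, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_grid <- function(vol, lo, hi) {
  vals <- vol$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- as.numeric(vol$origin + vol$direction %*% (vol$spacing * (lo - 1)))
  if (inherits(vol, "roi_mask"))
    roi_mask(vals, vol$spacing, origin, vol$direction, label = vol$label)
  else
    volume_grid(vals, vol$spacing, origin, vol$direction)
}

#' Crop all matrices of a case to a common bounding box
#'
#' Crops CT, dose and all masks to the bounding box of a non-empty envelope
#' mask (typically PTV plus the peritumoral ring), expanded by `margin_mm`
#' in every direction and clipped at the volume borders, so that all per-case
#' matrices end up with identical dimensions.
#'
#' @param case a `study_case` whose volumes are mutually aligned.
#' @param envelope `roi_mask` on the same grid.
#' @param margin_mm non-negative margin in mm (default 10).
#' @return a cropped `study_case`.
#' @export
crop_bundle <- function(case, envelope, margin_mm = 10) {
  stopifnot(inherits(case, "study_case"), inherits(envelope, "roi_mask"))
  stop_if_misaligned(case$ct, envelope, "ct and envelope")
  if (margin_mm < 0) stop("`margin_mm` must be non-negative")
  ci <- crop_indices(envelope$values, envelope$spacing, margin_mm)
  study_case(case$case_id,
             ct = crop_grid(case$ct, ci$lo, ci$hi),
             dose = crop_grid(case$dose, ci$lo, ci$hi),
             clinical_gtv = crop_grid(case$clinical_gtv, ci$lo, ci$hi),
             ptv = crop_grid(case$ptv, ci$lo, ci$hi),
             prescription_dose = case$prescription_dose,
             n_fractions = case$n_fractions,
             outcome = case$outcome)
}

#' Resample every matrix of a case onto one analysis grid
#'
#' CT and dose are resampled with trilinear interpolation, masks with
#' nearest-neighbour, all onto `spacing` (default 1 x 1 x 2 mm). Dose grids
#' exported on a coarser native grid should be passed through this step so
#' that all joint computations share the CT grid.
#'
#' @param case a `study_case`.
#' @param spacing target spacing in mm.
#' @return resampled `study_case`.
#' @export
resample_case <- function(case, spacing = c(1, 1, 2)) {
  study_case(case$case_id,
             ct = resample(case$ct, spacing, "linear"),
             dose = resample(case$dose, spacing, "linear"),
             clinical_gtv = resample(case$clinical_gtv, spacing, "nearest"),
             ptv = resample(case$ptv, spacing, "nearest"),
             prescription_dose = case$prescription_dose,
             n_fractions = case$n_fractions,
             outcome = case$outcome)
}
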
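#' Construct a volume grid
#'
#' A `volume_grid` is the carrier for every 3-D scalar field in the pipeline:
#' the planning CT (HU), the physical and biologically effective dose (Gy),
#' and the unitless CT--dose interaction matrices. It couples a 3-D array
#' with its voxel geometry (spacing in mm, physical origin, axis direction
#' matrix) so that all distance computations can be done in physical
#' millimetres, which matters for anisotropic voxels such as the default
#' 1 x 1 x 2 mm grid.
#'
#' @param values numeric 3-D array.
#' @param spacing numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin numeric length-3, physical coordinate (mm) of the centre of
#'   voxel (1,1,1).
#' @param direction 3 x 3 axis direction matrix (columns are the patient-space
#'   directions of the array axes); defaults to identity.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0),
                        direction = diag(3)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || length(values) == 0L)
    stop("`values` must be a non-empty 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  direction <- matrix(as.numeric(direction), 3, 3)
  structure(list(values = values, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid %dx%dx%d, spacing %.3gx%.3gx%.3g mm, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Construct a binary region-of-interest mask
#'
#' A `roi_mask` is a `volume_grid` whose values are restricted to {0, 1},
#' carrying a label naming which volume of interest it represents
#' (`semiGTV`, `PTV`, `RING`, `ISO50`, or a free label such as `GTV`).
#'
#' @param values 3-D array coercible to 0/1.
#' @param spacing,origin,direction voxel geometry, as [volume_grid()].
#' @param label character scalar naming the region.
#' @return an object of classes `roi_mask`, `volume_grid`.
#' @export
roi_mask <- function(values, spacing, origin = c(0, 0, 0),
                     direction = diag(3), label = "ROI") {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (!all(values %in% c(0, 1)))
    stop("mask values must be 0/1")
  vg <- volume_grid(values, spacing, origin, direction)
  vg$label <- as.character(label)[1]
  class(vg) <- c("roi_mask", "volume_grid")
  vg
}

#' Turn a volume into a mask by keeping its geometry
#' @param vol a `volume_grid` supplying geometry.
#' @param values 0/1 array on the same grid.
#' @param label region label.
#' @return `roi_mask`
#' @export
as_roi_mask <- function(vol, values, label = "ROI") {
  roi_mask(values, vol$spacing, vol$origin, vol$direction, label = label)
}

#' Number of voxels inside a mask
#' @param mask `roi_mask`
#' @return integer count
#' @export
mask_count <- function(mask) sum(mask$values > 0)

#' Test whether two volume grids are aligned
#'
#' Two grids are aligned when their array shapes match and their spacings,
#' origins and direction matrices agree within `tol` (mm).
#'
#' @param a,b `volume_grid` objects.
#' @param tol geometric tolerance in mm (default 1e-3).
#' @return logical scalar.
#' @export
grids_aligned <- function(a, b, tol = 1e-3) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$direction - b$direction) <= tol)
}

stop_if_misaligned <- function(a, b, what = "volumes") {
  if (!grids_aligned(a, b))
    stop(sprintf("%s are not on the same grid (shape/spacing/origin/direction mismatch)",
                 what))
  invisible(TRUE)
}

#' Outcome record for one case
#'
#' Binary treatment-failure label plus follow-up time and a competing-death
#' indicator; the unit of `time_months` is months since end of treatment.
#' A case cannot both fail and die of a competing cause at the same event
#' time: failure takes precedence in coding, so the two flags are exclusive.
#'
#' @param failure logical, treatment failure observed.
#' @param time_months non-negative follow-up / event time in months.
#' @param competing_death logical, death without prior failure.
#' @return an object of class `outcome_record`.
#' @export
outcome_record <- function(failure, time_months, competing_death = FALSE) {
  failure <- isTRUE(as.logical(failure))
  competing_death <- isTRUE(as.logical(competing_death))
  time_months <- as.numeric(time_months)
  if (!is.finite(time_months) || time_months < 0)
    stop("`time_months` must be a non-negative number")
  if (failure && competing_death)
    stop("`failure` and `competing_death` cannot both be TRUE")
  structure(list(failure = failure, time_months = time_months,
                 competing_death = competing_death),
            class = "outcome_record")
}

#' Bundle one patient / phantom case
#'
#' @param case_id character identifier.
#' @param ct planning CT `volume_grid` (HU).
#' @param dose total physical dose `volume_grid` (Gy) on the same grid as
#'   `ct` (resample first if the planning system exported a coarser grid).
#' @param clinical_gtv,ptv `roi_mask` objects aligned with `ct`.
#' @param prescription_dose prescription in Gy (> 0).
#' @param n_fractions number of fractions (>= 1).
#' @param outcome an [outcome_record()], or NULL when outcomes are joined
#'   later from a CSV.
#' @return an object of class `study_case`.
#' @export
study_case <- function(case_id, ct, dose, clinical_gtv, ptv,
                       prescription_dose, n_fractions, outcome = NULL) {
  stopifnot(inherits(ct, "volume_grid"), inherits(dose, "volume_grid"),
            inherits(clinical_gtv, "roi_mask"), inherits(ptv, "roi_mask"))
  stop_if_misaligned(ct, dose, "ct and dose")
  stop_if_misaligned(ct, clinical_gtv, "ct and clinical_gtv")
  stop_if_misaligned(ct, ptv, "ct and ptv")
  if (!is.numeric(prescription_dose) || prescription_dose <= 0)
    stop("`prescription_dose` must be > 0 Gy")
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("`n_fractions` must be a positive integer")
  if (!is.null(outcome) && !inherits(outcome, "outcome_record"))
    stop("`outcome` must be an outcome_record or NULL")
  structure(list(case_id = as.character(case_id)[1], ct = ct, dose = dose,
                 clinical_gtv = clinical_gtv, ptv = ptv,
                 prescription_dose = as.numeric(prescription_dose),
                 n_fractions = n_fractions, outcome = outcome),
            class = "study_case")
}

#' @export
print.study_case <- function(x, ...) {
  d <- dim(x$ct$values)
  cat(sprintf("<study_case %s: %dx%dx%d, %g Gy in %d fx, GTV %d vx, PTV %d vx>\n",
              x$case_id, d[1], d[2], d[3], x$prescription_dose, x$n_fractions,
              mask_count(x$clinical_gtv), mask_count(x$ptv)))
  invisible(x)
}
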
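## Euclidean distance transforms in physical mm (separable parabola
## lower-envelope algorithm), used for the peritumoral ring, PTV dilation
## and phantom dose falloff. Distances are measured between voxel centres,
## so anisotropic 1 x 1 x 2 mm grids are handled correctly.

dt1d_sq <- function(f, s) {
  n <- length(f)
  qs <- which(is.finite(f))
  if (length(qs) == 0L) return(rep(Inf, n))
  s2 <- s * s
  v <- integer(n + 1); z <- numeric(n + 2)
  k <- 1L; v[1] <- qs[1]; z[1] <- -Inf; z[2] <- Inf
  if (length(qs) > 1L) for (q in qs[-1]) {
    repeat {
      p <- v[k]
      sec <- ((f[q] + q * q * s2) - (f[p] + p * p * s2)) / (2 * s2 * (q - p))
      if (sec <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- sec; z[k + 1] <- Inf
  }
  d <- numeric(n); j <- 1L
  for (p in seq_len(n)) {
    while (z[j + 1] < p) j <- j + 1L
    d[p] <- s2 * (p - v[j])^2 + f[v[j]]
  }
  d
}

#' Euclidean distance map to a mask, in millimetres
#'
#' Exact distance from every voxel centre to the nearest voxel centre of the
#' mask, honouring anisotropic voxel spacing. Voxels inside the mask have
#' distance 0.
#'
#' @param mask a `roi_mask` (or any `volume_grid` treated as values > 0).
#' @return numeric 3-D array of distances (mm); `Inf` if the mask is empty.
#' @export
distance_map_mm <- function(mask) {
  vals <- mask$values; sp <- mask$spacing
  f <- array(ifelse(vals > 0, 0, Inf), dim = dim(vals))
  f <- apply(f, c(2, 3), dt1d_sq, sp[1])
  f <- aperm(apply(f, c(1, 3), dt1d_sq, sp[2]), c(2, 1, 3))
  f <- aperm(apply(f, c(1, 2), dt1d_sq, sp[3]), c(2, 3, 1))
  sqrt(f)
}

#' Semi-automatic gross tumor volume
#'
#' Restricts the clinician's GTV contour to voxels whose CT number lies in
#' a plausible tumor-tissue window, reducing inter-observer variability.
#' Bounds are inclusive; no connectivity filtering is applied.
#'
#' @param ct planning CT `volume_grid` (HU).
#' @param clinical_gtv `roi_mask` aligned with `ct`.
#' @param hu_low,hu_high HU window, default -550 to 2000.
#' @return `roi_mask` labelled `semiGTV`; if empty, it carries
#'   `empty = TRUE` and a warning is raised (features for that region are
#'   recorded as missing downstream).
#' @export
semi_auto_gtv <- function(ct, clinical_gtv, hu_low = -550, hu_high = 2000) {
  stop_if_misaligned(ct, clinical_gtv, "ct and clinical_gtv")
  if (hu_low >= hu_high) stop("`hu_low` must be below `hu_high`")
  keep <- (clinical_gtv$values > 0) & (ct$values >= hu_low) &
    (ct$values <= hu_high)
  m <- as_roi_mask(ct, array(as.numeric(keep), dim = dim(ct$values)),
                   label = "semiGTV")
  if (mask_count(m) == 0L) {
    warning("semi-automatic GTV is empty: no clinical-GTV voxel in the HU window")
    m$empty <- TRUE
  }
  m
}

#' Peritumoral ring outside the PTV
#'
#' The shell of tissue outside the PTV whose physical distance to the
#' nearest PTV voxel centre is at most `outer_mm` (default 20 mm, i.e. the
#' 2 cm peritumoral region). Always disjoint from the PTV and clipped at
#' the volume borders.
#'
#' @param ptv non-empty `roi_mask`.
#' @param outer_mm ring thickness in mm.
#' @return `roi_mask` labelled `RING`.
#' @export
peritumoral_ring <- function(ptv, outer_mm = 20) {
  stopifnot(inherits(ptv, "roi_mask"))
  if (mask_count(ptv) == 0L) stop("PTV mask is empty")
  if (outer_mm < 0) stop("`outer_mm` must be non-negative")
  d <- distance_map_mm(ptv)
  ring <- (d > 0) & (d <= outer_mm)
  as_roi_mask(ptv, array(as.numeric(ring), dim = dim(d)), label = "RING")
}

#' ISO50 region: at least half the prescription dose, outside the PTV
#'
#' Voxels receiving at least 50 percent of the prescription dose
#' (inclusive threshold on total physical dose) that do not belong to the
#' PTV. In SBRT this captures the steep dose-falloff region around the
#' target.
#'
#' @param dose total physical dose `volume_grid` (Gy).
#' @param prescription prescription dose in Gy (> 0).
#' @param ptv `roi_mask` aligned with `dose`.
#' @return `roi_mask` labelled `ISO50`.
#' @export
iso50 <- function(dose, prescription, ptv) {
  stop_if_misaligned(dose, ptv, "dose and ptv")
  if (prescription <= 0) stop("`prescription` must be > 0 Gy")
  keep <- (dose$values >= 0.5 * prescription) & (ptv$values == 0)
  as_roi_mask(dose, array(as.numeric(keep), dim = dim(dose$values)),
              label = "ISO50")
}

#' Build the four volumes of interest for a case
#'
#' @param case preprocessed `study_case`.
#' @param hu_low,hu_high HU window for the semi-automatic GTV.
#' @param ring_mm peritumoral ring thickness (mm).
#' @return named list of `roi_mask`: `semiGTV`, `PTV`, `RING`, `ISO50`.
#' @export
build_rois <- function(case, hu_low = -550, hu_high = 2000, ring_mm = 20) {
  ptv <- case$ptv
  ptv$label <- "PTV"
  list(semiGTV = suppressWarnings(
         semi_auto_gtv(case$ct, case$clinical_gtv, hu_low, hu_high)),
       PTV = ptv,
       RING = peritumoral_ring(ptv, ring_mm),
       ISO50 = iso50(case$dose, case$prescription_dose, ptv))
}
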
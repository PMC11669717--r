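#' Per-voxel alpha/beta ratio map
#'
#' Voxels inside the PTV are treated as cancerous tissue (alpha/beta
#' 10 Gy by convention), everything outside as late-responding normal
#' tissue (3 Gy). No electron-density modulation is applied: a binary
#' PTV rule is the only widely accepted voxel-level assignment.
#'
#' @param ptv `roi_mask`.
#' @param ab_inside alpha/beta (Gy) inside the PTV, default 10.
#' @param ab_outside alpha/beta (Gy) outside, default 3.
#' @return `volume_grid` of alpha/beta ratios (Gy) on the PTV grid.
#' @export
alpha_beta_map <- function(ptv, ab_inside = 10, ab_outside = 3) {
  stopifnot(inherits(ptv, "roi_mask"))
  if (ab_inside <= 0 || ab_outside <= 0)
    stop("alpha/beta ratios must be strictly positive")
  vals <- ifelse(ptv$values > 0, ab_inside, ab_outside)
  volume_grid(array(vals, dim = dim(ptv$values)), ptv$spacing, ptv$origin,
              ptv$direction)
}

#' Voxelated biologically effective dose
#'
#' Applies the linear-quadratic model voxel by voxel:
#' \deqn{BED = n d (1 + d / (\alpha/\beta))}
#' where `n` is the number of fractions and `d` the physical dose per
#' fraction at the voxel. The input grid holds the plan's *total* physical
#' dose, so `d = total / n`. BED is at least the physical dose everywhere,
#' with equality only at zero dose, and approaches the physical dose as
#' alpha/beta grows.
#'
#' @param total_dose `volume_grid`, total physical dose (Gy).
#' @param n_fractions positive integer.
#' @param ab `volume_grid` of per-voxel alpha/beta ratios (Gy), aligned with
#'   the dose; see [alpha_beta_map()].
#' @return `volume_grid` of BED (Gy). Negative dose voxels (interpolation
#'   artefacts) are clipped to 0 and their count reported via a message.
#' @export
compute_bed <- function(total_dose, n_fractions, ab) {
  stopifnot(inherits(total_dose, "volume_grid"), inherits(ab, "volume_grid"))
  stop_if_misaligned(total_dose, ab, "dose and alpha/beta map")
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("`n_fractions` must be a positive integer")
  tot <- total_dose$values
  neg <- sum(tot < 0)
  if (neg > 0) {
    message(sprintf("compute_bed: clipped %d negative dose voxels to 0", neg))
    tot[tot < 0] <- 0
  }
  d <- tot / n_fractions
  bed <- tot * (1 + d / ab$values)
  volume_grid(array(bed, dim = dim(tot)), total_dose$spacing,
              total_dose$origin, total_dose$direction)
}
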
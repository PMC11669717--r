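## Voxelated CT--BED interaction matrices.
##
## At every voxel a pair of 3x3x3 patches (index space, edge-replicated at
## the borders) is read from the aligned CT and BED volumes and summarised
## by one of five metrics: joint entropy, Jensen-Shannon divergence,
## first-order Wasserstein distance, Spearman rank correlation, or the
## degenerate pairwise product. The scalar is written back at the centre
## voxel, so each interaction matrix keeps the shape and geometry of its
## inputs. The sliding-window engine below is vectorised over all voxels at
## once; the per-patch functions are the scalar reference path and the two
## must agree (tested to 1e-10).

interaction_metrics <- c("ENTROPY", "JSD", "MULTIPLY", "SPEARMAN", "WASSERSTEIN")

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

#' Extract a CT/BED patch pair around one voxel
#'
#' 3x3x3 neighbourhoods (for `half_width = 1`) in index space; voxels
#' beyond the border are filled by edge replication so every voxel of the
#' volume, including corners, yields a full 27-value patch.
#'
#' @param ct,bed aligned `volume_grid`s.
#' @param center integer voxel index triple (1-based).
#' @param half_width neighbourhood half width in voxels (default 1).
#' @return object of class `patch_pair`: `ct_patch`, `bed_patch` (length-27
#'   vectors for the default width) and `center`.
#' @export
extract_patch_pair <- function(ct, bed, center, half_width = 1L) {
  stop_if_misaligned(ct, bed, "ct and bed")
  d <- dim(ct$values)
  center <- as.integer(center)
  if (length(center) != 3L || any(center < 1L) || any(center > d))
    stop("`center` is outside the volume")
  hw <- as.integer(half_width)
  ix <- clamp_idx(center[1] + (-hw:hw), d[1])
  iy <- clamp_idx(center[2] + (-hw:hw), d[2])
  iz <- clamp_idx(center[3] + (-hw:hw), d[3])
  structure(list(ct_patch = as.vector(ct$values[ix, iy, iz]),
                 bed_patch = as.vector(bed$values[ix, iy, iz]),
                 center = center),
            class = "patch_pair")
}

# min-max normalize a vector to [0,1]; constant input maps to all zeros so
# that a constant patch puts all histogram mass in the first bin
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

hist_probs <- function(x01, n_bins) {
  b <- pmin(floor(x01 * n_bins) + 1L, n_bins)
  tabulate(b, nbins = n_bins) / length(x01)
}

#' Per-patch marginal histograms
#'
#' Each patch is min-max normalised to [0,1] over its own values (a
#' constant patch maps to bin 1) and histogrammed into `n_bins` equal-width
#' bins; each returned vector sums to 1.
#'
#' @param p a `patch_pair`.
#' @param n_bins number of bins (default 8; must be >= 2).
#' @return list with probability vectors `ct` and `bed`.
#' @export
patch_histograms <- function(p, n_bins = 8L) {
  if (n_bins < 2L) stop("`n_bins` must be at least 2")
  list(ct = hist_probs(minmax01(p$ct_patch), n_bins),
       bed = hist_probs(minmax01(p$bed_patch), n_bins))
}

#' Spearman rank correlation of a patch pair
#'
#' Rank correlation of the paired patch values (average ranks for ties),
#' measuring the local monotonic relationship between CT and dose. If
#' either patch is constant the correlation is undefined and 0 is returned
#' by convention.
#'
#' @param p a `patch_pair`.
#' @return value in [-1, 1].
#' @export
patch_spearman <- function(p) {
  if (length(unique(p$ct_patch)) < 2L || length(unique(p$bed_patch)) < 2L)
    return(0)
  stats::cor(p$ct_patch, p$bed_patch, method = "spearman")
}

#' Joint entropy of a patch pair
#'
#' Shannon entropy (bits) of the 2-D joint histogram of the paired,
#' per-patch-normalised (ct, bed) values on an `n_bins` x `n_bins` grid.
#' Captures the local co-complexity of image and dose; 0 when both patches
#' are constant, at most log2(27) for the default patch.
#'
#' @param p a `patch_pair`.
#' @param n_bins marginal bin count (default 8).
#' @return entropy in bits, >= 0.
#' @export
patch_entropy <- function(p, n_bins = 8L) {
  a <- pmin(floor(minmax01(p$ct_patch) * n_bins) + 1L, n_bins)
  b <- pmin(floor(minmax01(p$bed_patch) * n_bins) + 1L, n_bins)
  joint <- tabulate((a - 1L) * n_bins + b, nbins = n_bins * n_bins)
  pr <- joint[joint > 0] / length(a)
  -sum(pr * log2(pr))
}

#' Jensen-Shannon divergence of a patch pair
#'
#' JSD (log base 2, hence bounded in [0, 1]) between the two marginal
#' histograms of [patch_histograms()]; 0 iff the histograms coincide, 1 for
#' disjoint support.
#'
#' @param p a `patch_pair`.
#' @param n_bins marginal bin count (default 8).
#' @return value in [0, 1].
#' @export
patch_jsd <- function(p, n_bins = 8L) {
  h <- patch_histograms(p, n_bins)
  jsd_vec(h$ct, h$bed)
}

jsd_vec <- function(P, Q) {
  M <- (P + Q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / M[i]))
  }
  max(0, min(1, 0.5 * kl(P) + 0.5 * kl(Q)))
}

#' First-order Wasserstein distance of a patch pair
#'
#' W1 distance between the empirical distributions of the per-patch
#' min-max-normalised values; with equal sample counts this is the mean
#' absolute difference of the sorted samples. Normalisation makes the HU
#' and Gy scales comparable; set `normalize = FALSE` for the raw-scale
#' distance.
#'
#' @param p a `patch_pair`.
#' @param normalize normalise each patch to [0,1] first (default TRUE).
#' @return value >= 0 (<= 1 when normalised).
#' @export
patch_wasserstein <- function(p, normalize = TRUE) {
  a <- p$ct_patch; b <- p$bed_patch
  if (normalize) { a <- minmax01(a); b <- minmax01(b) }
  mean(abs(sort(a) - sort(b)))
}

#' Pairwise multiplication matrix
#'
#' Element-wise product of the CT and BED volumes; no patching or
#' normalisation.
#'
#' @param ct,bed aligned `volume_grid`s.
#' @return `volume_grid` of products.
#' @export
pairwise_multiply <- function(ct, bed) {
  stop_if_misaligned(ct, bed, "ct and bed")
  volume_grid(ct$values * bed$values, ct$spacing, ct$origin, ct$direction)
}

## ---- vectorised sliding-window engine --------------------------------------

# 27 x N matrix of edge-replicated neighbours for every voxel (columns in
# array order)
neighbor_matrix <- function(A, hw = 1L) {
  d <- dim(A)
  offs <- as.matrix(expand.grid(dx = -hw:hw, dy = -hw:hw, dz = -hw:hw))
  K <- nrow(offs)
  M <- matrix(0, K, prod(d))
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  for (r in seq_len(K)) {
    M[r, ] <- as.vector(A[clamp_idx(sx + offs[r, 1], d[1]),
                          clamp_idx(sy + offs[r, 2], d[2]),
                          clamp_idx(sz + offs[r, 3], d[3])])
  }
  M
}

# column-wise fractional ranks with average ties (K small, N large)
col_ranks <- function(M) {
  K <- nrow(M)
  R <- matrix(0, K, ncol(M))
  for (i in seq_len(K)) {
    xi <- M[i, ]
    acc <- 0.5
    for (j in seq_len(K)) {
      xj <- M[j, ]
      acc <- acc + (xj < xi) + 0.5 * (xj == xi)
    }
    R[i, ] <- acc
  }
  R
}

# column-wise min-max normalisation to [0,1]; constant columns -> 0
col_minmax01 <- function(M) {
  lo <- apply(M, 2, min); hi <- apply(M, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  sweep(sweep(M, 2, lo, "-"), 2, rng, "/")
}

col_sort <- function(M) {
  K <- nrow(M); N <- ncol(M)
  o <- order(rep(seq_len(N), each = K), M)
  matrix(M[o], K, N)
}

# column-wise histogram probabilities: n_bins x N
col_hist <- function(M01, n_bins) {
  K <- nrow(M01)
  B <- pmin(floor(M01 * n_bins) + 1L, n_bins)
  H <- matrix(0, n_bins, ncol(M01))
  for (b in seq_len(n_bins)) H[b, ] <- colSums(B == b)
  H / K
}

sw_spearman <- function(Mct, Mbed) {
  K <- nrow(Mct)
  Ra <- col_ranks(Mct); Rb <- col_ranks(Mbed)
  ma <- colMeans(Ra); mb <- colMeans(Rb)
  va <- colMeans(Ra^2) - ma^2
  vb <- colMeans(Rb^2) - mb^2
  cov <- colMeans(Ra * Rb) - ma * mb
  den <- sqrt(va * vb)
  out <- ifelse(den > 0, cov / den, 0)
  pmin(pmax(out, -1), 1)
}

sw_entropy <- function(Mct, Mbed, n_bins) {
  K <- nrow(Mct)
  Ba <- pmin(floor(col_minmax01(Mct) * n_bins) + 1L, n_bins)
  Bb <- pmin(floor(col_minmax01(Mbed) * n_bins) + 1L, n_bins)
  J <- (Ba - 1L) * n_bins + Bb
  H <- 0
  for (cell in seq_len(n_bins * n_bins)) {
    p <- colSums(J == cell) / K
    i <- p > 0
    if (any(i)) {
      h <- numeric(length(p)); h[i] <- -p[i] * log2(p[i])
      H <- H + h
    }
  }
  H
}

sw_jsd <- function(Mct, Mbed, n_bins) {
  P <- col_hist(col_minmax01(Mct), n_bins)
  Q <- col_hist(col_minmax01(Mbed), n_bins)
  M <- (P + Q) / 2
  term <- function(A) {
    T <- matrix(0, nrow(A), ncol(A))
    i <- A > 0
    T[i] <- A[i] * log2(A[i] / M[i])
    colSums(T)
  }
  pmin(pmax(0.5 * term(P) + 0.5 * term(Q), 0), 1)
}

sw_wasserstein <- function(Mct, Mbed) {
  As <- col_sort(col_minmax01(Mct))
  Bs <- col_sort(col_minmax01(Mbed))
  colMeans(abs(As - Bs))
}

#' Compute one voxelated interaction matrix
#'
#' Applies the chosen per-patch metric at every voxel of the aligned CT and
#' BED volumes (edge-replicated 3x3x3 patches) and returns a volume of the
#' same shape and geometry. `MULTIPLY` is the patch-free element-wise
#' product.
#'
#' @param ct,bed aligned `volume_grid`s.
#' @param metric one of `"ENTROPY"`, `"JSD"`, `"MULTIPLY"`, `"SPEARMAN"`,
#'   `"WASSERSTEIN"`.
#' @param n_bins histogram bin count for ENTROPY/JSD (default 8).
#' @param half_width patch half width (default 1, i.e. 3x3x3).
#' @param entropy_mode `"joint"` (entropy of the paired 2-D histogram,
#'   default) or `"marginal_diff"` (absolute difference of the two marginal
#'   entropies).
#' @return `volume_grid` with a `metric` field, class `interaction_volume`.
#' @export
interaction_volume <- function(ct, bed, metric, n_bins = 8L, half_width = 1L,
                               entropy_mode = c("joint", "marginal_diff")) {
  stop_if_misaligned(ct, bed, "ct and bed")
  entropy_mode <- match.arg(entropy_mode)
  if (!metric %in% interaction_metrics)
    stop(sprintf("unknown interaction metric '%s'", metric))
  d <- dim(ct$values)
  if (metric == "MULTIPLY") {
    out <- pairwise_multiply(ct, bed)
  } else {
    Mct <- neighbor_matrix(ct$values, half_width)
    Mbed <- neighbor_matrix(bed$values, half_width)
    v <- switch(metric,
      SPEARMAN = sw_spearman(Mct, Mbed),
      WASSERSTEIN = sw_wasserstein(Mct, Mbed),
      JSD = sw_jsd(Mct, Mbed, n_bins),
      ENTROPY = if (entropy_mode == "joint") sw_entropy(Mct, Mbed, n_bins)
                else {
                  marg <- function(M) {
                    H <- col_hist(col_minmax01(M), n_bins)
                    colSums(ifelse(H > 0, -H * log2(H), 0))
                  }
                  abs(marg(Mct) - marg(Mbed))
                })
    out <- volume_grid(array(v, dim = d), ct$spacing, ct$origin, ct$direction)
  }
  out$metric <- metric
  class(out) <- c("interaction_volume", class(out))
  out
}

#' Compute all five interaction matrices for a case
#'
#' @param ct planning CT `volume_grid`.
#' @param bed BED `volume_grid` from [compute_bed()].
#' @param metrics subset of the five metric names (default all).
#' @param n_bins histogram bins for ENTROPY/JSD.
#' @return named list of `interaction_volume`s.
#' @export
compute_interactions <- function(ct, bed, metrics = interaction_metrics,
                                 n_bins = 8L) {
  stop_if_misaligned(ct, bed, "ct and bed")
  bad <- setdiff(metrics, interaction_metrics)
  if (length(bad)) stop(sprintf("unknown interaction metric '%s'", bad[1]))
  out <- list()
  d <- dim(ct$values)
  patch_metrics <- setdiff(metrics, "MULTIPLY")
  if (length(patch_metrics)) {
    # the neighbour matrices are shared across all patch metrics
    Mct <- neighbor_matrix(ct$values, 1L)
    Mbed <- neighbor_matrix(bed$values, 1L)
    for (m in patch_metrics) {
      v <- switch(m,
        SPEARMAN = sw_spearman(Mct, Mbed),
        WASSERSTEIN = sw_wasserstein(Mct, Mbed),
        JSD = sw_jsd(Mct, Mbed, n_bins),
        ENTROPY = sw_entropy(Mct, Mbed, n_bins))
      vol <- volume_grid(array(v, dim = d), ct$spacing, ct$origin,
                         ct$direction)
      vol$metric <- m
      class(vol) <- c("interaction_volume", class(vol))
      out[[m]] <- vol
    }
  }
  if ("MULTIPLY" %in% metrics)
    out$MULTIPLY <- interaction_volume(ct, bed, "MULTIPLY")
  out[metrics]
}
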
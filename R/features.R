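## Standardized radiomics feature extraction.
##
## Every (matrix, ROI) pair yields the same 105-feature vector: 14 shape
## descriptors computed from the mask alone, 18 first-order statistics, and
## 73 texture features from five gray-level matrices (22 GLCM, 16 GLRLM,
## 16 GLSZM, 14 GLDM, 5 NGTDM). The definitions follow the IBSI-aligned
## conventions of the standard radiomics toolkits; of the usual 24 GLCM
## features, SumAverage (linearly redundant with JointAverage on symmetric
## matrices) and MCC (unstable on small regions) are excluded so the
## non-shape count lands on 91. The shipped feature list is a versioned
## JSON in inst/extdata so the count is auditable.

#' The canonical 105-feature name vector
#'
#' Names are `<class>__<feature>`; table columns prefix them with
#' `<matrix>__<roi>__`. 14 shape + 18 first-order + 73 texture features.
#'
#' @return character vector of length 105.
#' @export
feature_names_105 <- function() {
  shape <- c("VoxelVolume", "VoxelCount", "SurfaceArea", "SurfaceVolumeRatio",
             "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
             "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
             "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
             "Elongation", "Flatness")
  fo <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
          "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
          "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
          "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")
  glcm <- c("Autocorrelation", "JointAverage", "ClusterProminence",
            "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
            "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
            "Id", "Idm", "Idmn", "Idn", "InverseVariance", "JointEnergy",
            "JointEntropy", "MaximumProbability", "SumEntropy", "SumSquares",
            "Imc1", "Imc2")
  glrlm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
             "RunLengthNonUniformityNormalized", "RunPercentage",
             "GrayLevelVariance", "RunVariance", "RunEntropy",
             "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
             "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
             "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  glszm <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
             "SizeZoneNonUniformityNormalized", "ZonePercentage",
             "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
             "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
             "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
             "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  gldm <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
            "GrayLevelNonUniformity", "DependenceNonUniformity",
            "DependenceNonUniformityNormalized", "GrayLevelVariance",
            "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
            "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
            "SmallDependenceHighGrayLevelEmphasis",
            "LargeDependenceLowGrayLevelEmphasis",
            "LargeDependenceHighGrayLevelEmphasis")
  ngtdm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  c(paste0("Shape__", shape), paste0("FirstOrder__", fo),
    paste0("GLCM__", glcm), paste0("GLRLM__", glrlm),
    paste0("GLSZM__", glszm), paste0("GLDM__", gldm),
    paste0("NGTDM__", ngtdm))
}

feature_classes <- c("Shape", "FirstOrder", "GLCM", "GLRLM", "GLSZM", "GLDM",
                     "NGTDM")

#' Feature extraction configuration
#'
#' Gray-level discretisation: CT-like sources use a fixed bin *width*
#' (default 25 HU); BED and the interaction matrices, whose dynamic ranges
#' differ by orders of magnitude, use a fixed bin *count* (default 32).
#' No image filters (wavelet/LoG) are applied: the 105-feature vector is
#' computed on the original matrix only.
#'
#' @param bin_mode `"width"` or `"count"`.
#' @param bin_width bin width in source units (used when mode is width).
#' @param n_bins number of gray levels (used when mode is count).
#' @param classes feature classes to compute; defaults to all seven. A
#'   reduced set (e.g. shape + first-order) gives a proportionally shorter
#'   vector, used for fast large-cohort runs.
#' @return list of class `dosimix_feature_config`.
#' @export
feature_config <- function(bin_mode = c("count", "width"), bin_width = 25,
                           n_bins = 32L, classes = feature_classes) {
  bin_mode <- match.arg(bin_mode)
  classes <- match.arg(classes, feature_classes, several.ok = TRUE)
  structure(list(bin_mode = bin_mode, bin_width = bin_width,
                 n_bins = as.integer(n_bins), classes = classes),
            class = "dosimix_feature_config")
}

#' Default per-source extraction configs
#' @param source matrix name (`"CT"`, `"BED"`, or an interaction metric).
#' @param classes feature classes to compute.
#' @return `dosimix_feature_config`
#' @export
default_feature_config <- function(source, classes = feature_classes) {
  if (identical(source, "CT"))
    feature_config("width", bin_width = 25, classes = classes)
  else
    feature_config("count", n_bins = 32L, classes = classes)
}

# discretize ROI values to integer gray levels 1..Ng
discretize_gray <- function(x, config) {
  if (config$bin_mode == "width") {
    w <- config$bin_width
    g <- floor(x / w) - floor(min(x) / w) + 1
  } else {
    r <- range(x)
    if (r[2] == r[1]) g <- rep(1, length(x))
    else g <- pmin(floor((x - r[1]) / (r[2] - r[1]) * config$n_bins) + 1,
                   config$n_bins)
  }
  as.integer(g)
}

## ---- shape -----------------------------------------------------------------

# exposed-face surface area of a binary array with given spacing
mask_surface_area <- function(m, sp) {
  d <- dim(m)
  areas <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  total <- 0
  for (a in 1:3) {
    # neighbours along +a and -a with zero padding at the borders
    up <- arr_shift_fill(m, ifelse(1:3 == a, 1, 0), fill = 0)
    dn <- arr_shift_fill(m, ifelse(1:3 == a, -1, 0), fill = 0)
    total <- total + areas[a] * (sum(m == 1 & up == 0) + sum(m == 1 & dn == 0))
  }
  total
}

max_pair_dist <- function(P) {
  n <- nrow(P)
  if (n < 2L) return(0)
  best <- 0
  step <- max(1L, floor(4e6 / n))
  for (s in seq(1L, n, by = step)) {
    e <- min(s + step - 1L, n)
    blk <- P[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(P^2), "+") - 2 * tcrossprod(blk, P)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

# indices of the 2-D convex hull vertices (degenerate sets pass through)
hull2d_idx <- function(P2) {
  if (nrow(P2) < 3L) return(seq_len(nrow(P2)))
  h <- tryCatch(grDevices::chull(P2[, 1], P2[, 2]), error = function(e) NULL)
  if (is.null(h) || !length(h)) seq_len(nrow(P2)) else h
}

# The farthest pair of a 3-D point set lies on its convex hull, and every
# hull vertex is also a 2-D hull vertex within its own slice, so per-slice
# 2-D hulls give an exact (up to distance ties) candidate set at a fraction
# of the all-pairs cost.
hull_candidates <- function(S, idx, axis) {
  other <- setdiff(1:3, axis)
  parts <- split(seq_len(nrow(S)), idx[, axis])
  keep <- unlist(lapply(parts, function(rows) {
    rows[hull2d_idx(S[rows, other, drop = FALSE])]
  }), use.names = FALSE)
  S[keep, , drop = FALSE]
}

shape_features <- function(mask_vals, sp) {
  n <- sum(mask_vals > 0)
  vv <- prod(sp)
  vol <- n * vv
  sa <- mask_surface_area(mask_vals, sp)
  idx <- which(mask_vals > 0, arr.ind = TRUE)
  P <- sweep(idx - 1, 2, sp, "*")   # physical coords (mm)
  # surface voxels only, for the diameter features
  interior <- array(TRUE, dim(mask_vals))
  for (a in 1:3) {
    up <- arr_shift_fill(mask_vals, ifelse(1:3 == a, 1, 0), fill = 0)
    dn <- arr_shift_fill(mask_vals, ifelse(1:3 == a, -1, 0), fill = 0)
    interior <- interior & up > 0 & dn > 0
  }
  sidx <- which(mask_vals > 0 & !interior, arr.ind = TRUE)
  if (nrow(sidx) == 0L) sidx <- idx
  S <- sweep(sidx - 1, 2, sp, "*")
  d3 <- max_pair_dist(hull_candidates(S, sidx, 3))
  max2d <- function(keep_axis) {
    other <- setdiff(1:3, keep_axis)
    parts <- split(seq_len(nrow(S)), sidx[, keep_axis])
    m <- 0
    for (rows in parts) {
      P2 <- S[rows, other, drop = FALSE]
      m <- max(m, max_pair_dist(P2[hull2d_idx(P2), , drop = FALSE]))
    }
    m
  }
  d_slice <- max2d(3)   # in-plane (x,y) within an axial slice
  d_col <- max2d(2)     # (x,z) within a coronal plane
  d_row <- max2d(1)     # (y,z) within a sagittal plane
  if (n > 1) {
    ev <- sort(pmax(eigen(stats::cov(P) * (n - 1) / n,
                          symmetric = TRUE)$values, 0), decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  sph <- if (sa > 0) (36 * pi * vol^2)^(1 / 3) / sa else NA_real_
  c(VoxelVolume = vol, VoxelCount = n, SurfaceArea = sa,
    SurfaceVolumeRatio = if (vol > 0) sa / vol else NA_real_,
    Sphericity = sph, Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d_slice, Maximum2DDiameterColumn = d_col,
    Maximum2DDiameterRow = d_row,
    MajorAxisLength = axes[1], MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_)
}

## ---- first order -----------------------------------------------------------

firstorder_features <- function(x, g, voxel_volume) {
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  mid <- x[x >= q[1] & x <= q[4]]
  p <- tabulate(g) / n
  p <- p[p > 0]
  sk <- if (v > 0) mean((x - m)^3) / v^1.5 else 0
  ku <- if (v > 0) mean((x - m)^4) / v^2 else 0
  c(Energy = sum(x^2), TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p)), Minimum = min(x),
    Percentile10 = q[1], Percentile90 = q[4], Maximum = max(x),
    Mean = m, Median = stats::median(x), InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x), MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    RootMeanSquared = sqrt(mean(x^2)), Skewness = sk, Kurtosis = ku,
    Variance = v, Uniformity = sum(p^2))
}

## ---- gray-level matrix machinery ------------------------------------------

# out[v] = A[v + off], `fill` beyond borders
arr_shift_fill <- function(A, off, fill = NA_real_) {
  d <- dim(A)
  out <- array(fill, d)
  src <- lapply(1:3, function(a) seq_len(d[a]) + off[a])
  dv <- lapply(1:3, function(a) which(src[[a]] >= 1L & src[[a]] <= d[a]))
  if (all(lengths(dv) > 0))
    out[dv[[1]], dv[[2]], dv[[3]]] <-
      A[src[[1]][dv[[1]]], src[[2]][dv[[2]]], src[[3]][dv[[3]]]]
  out
}

offsets26 <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
}

offsets13 <- function() {
  o <- offsets26()
  keep <- (o[, 3] > 0) | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
}

glcm_features_one <- function(P) {
  # P: symmetric normalized co-occurrence matrix (Ng x Ng), sums to 1
  Ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  sdx <- sqrt(sum((i - mux)^2 * P)); sdy <- sqrt(sum((j - muy)^2 * P))
  pd <- sapply(0:(Ng - 1), function(k) sum(P[abs(i - j) == k]))
  ps <- sapply(2:(2 * Ng), function(k) sum(P[(i + j) == k]))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  da <- sum((0:(Ng - 1)) * pd)
  hx <- ent(px); hy <- ent(py); hxy <- ent(as.vector(P))
  pxy <- outer(px, py)
  pos <- P > 0 & pxy > 0
  hxy1 <- -sum(P[pos] * log2(pxy[pos]))
  pos2 <- pxy > 0
  hxy2 <- -sum(pxy[pos2] * log2(pxy[pos2]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  offd <- i != j
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sdx > 0 && sdy > 0)
      (sum(i * j * P) - mux * muy) / (sdx * sdy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pd),
    DifferenceVariance = sum(((0:(Ng - 1)) - da)^2 * pd),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / Ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    InverseVariance = sum(P[offd] / (i[offd] - j[offd])^2),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MaximumProbability = max(P),
    SumEntropy = ent(ps),
    SumSquares = sum((i - mux)^2 * P),
    Imc1 = imc1, Imc2 = imc2)
}

rl_features_one <- function(counts, Np, prefix = c("Run", "Area")) {
  # counts: Ng x max-length matrix of (gray level, run length / zone size)
  i <- row(counts); l <- col(counts)
  Nr <- sum(counts)
  if (Nr == 0) return(rep(NA_real_, 16))
  p <- counts / Nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  pp <- p[p > 0]
  c(sum(counts / l^2) / Nr,                    # short emphasis
    sum(counts * l^2) / Nr,                    # long emphasis
    sum(rowSums(counts)^2) / Nr,               # gray-level non-uniformity
    sum(rowSums(counts)^2) / Nr^2,
    sum(colSums(counts)^2) / Nr,               # length non-uniformity
    sum(colSums(counts)^2) / Nr^2,
    Nr / Np,                                   # run / zone percentage
    sum((i - mu_i)^2 * p),
    sum((l - mu_l)^2 * p),
    -sum(pp * log2(pp)),
    sum(counts / i^2) / Nr,
    sum(counts * i^2) / Nr,
    sum(counts / (i^2 * l^2)) / Nr,
    sum(counts * i^2 / l^2) / Nr,
    sum(counts * l^2 / i^2) / Nr,
    sum(counts * i^2 * l^2) / Nr)
}

# run lengths along one direction by pointer jumping; G has NA outside mask
runlength_counts <- function(G, off, Ng, lin_idx) {
  nxt <- arr_shift_fill(lin_idx, off, fill = 0)
  gnxt <- arr_shift_fill(G, off)
  same_f <- !is.na(G) & !is.na(gnxt) & G == gnxt
  n <- length(G)
  p <- ifelse(as.vector(same_f), as.vector(nxt), 0L)
  L <- rep(1L, n)
  while (TRUE) {
    has <- which(p > 0L)
    if (!length(has)) break
    L[has] <- L[has] + L[p[has]]
    p[has] <- p[p[has]]
  }
  gprv <- arr_shift_fill(G, -off)
  starts <- !is.na(G) & !(!is.na(gprv) & G == gprv)
  sv <- which(as.vector(starts))
  g <- as.vector(G)[sv]; len <- L[sv]
  maxlen <- max(len)
  counts <- matrix(0, Ng, maxlen)
  t <- tabulate((g - 1L) * maxlen + len, nbins = Ng * maxlen)
  matrix(t, Ng, maxlen, byrow = TRUE)
}

# connected components of iso-intensity zones (26-connectivity) by
# min-label propagation with pointer jumping; returns (gray, size) pairs
zone_table <- function(G, Ng) {
  d <- dim(G)
  n <- length(G)
  lab <- ifelse(is.na(as.vector(G)), 0L, seq_len(n))
  offs <- offsets26()
  lin <- array(seq_len(n), d)
  # same-gray neighbour edges (i -> j), one pair of index vectors per offset;
  # within an offset the source indices are unique, so pmin-scatter is valid
  edges <- lapply(seq_len(nrow(offs)), function(r) {
    nb_g <- arr_shift_fill(G, offs[r, ])
    nb_i <- arr_shift_fill(lin, offs[r, ], fill = 0)
    ok <- which(as.vector(!is.na(G) & !is.na(nb_g) & G == nb_g))
    list(i = ok, j = as.vector(nb_i)[ok])
  })
  m <- which(lab > 0L)
  repeat {
    old <- lab
    for (e in edges) lab[e$i] <- pmin(lab[e$i], lab[e$j])
    for (k in 1:2) lab[m] <- lab[lab[m]]
    if (identical(lab, old)) break
  }
  m <- which(lab > 0L)
  roots <- lab[m]
  sizes <- tabulate(roots, nbins = n)
  rid <- which(sizes > 0)
  data.frame(gray = as.vector(G)[rid], size = sizes[rid])
}

texture_features <- function(G, Ng, classes) {
  # G: 3-D array of gray levels 1..Ng, NA outside the ROI
  d <- dim(G)
  n <- length(G)
  Np <- sum(!is.na(G))
  lin_idx <- array(seq_len(n), d)
  dirs <- offsets13()
  out <- c()
  if ("GLCM" %in% classes) {
    acc <- 0
    used <- 0
    for (r in seq_len(nrow(dirs))) {
      gn <- arr_shift_fill(G, dirs[r, ])
      ok <- !is.na(G) & !is.na(gn)
      if (!any(ok)) next
      a <- G[ok]; b <- gn[ok]
      C <- matrix(tabulate((a - 1L) * Ng + b, nbins = Ng * Ng), Ng, Ng,
                  byrow = TRUE)
      C <- C + t(C)
      acc <- acc + glcm_features_one(C / sum(C))
      used <- used + 1
    }
    glcm <- if (used > 0) acc / used else
      stats::setNames(rep(NA_real_, 22), names(glcm_features_one(diag(2) / 2)))
    out <- c(out, stats::setNames(glcm, paste0("GLCM__", names(glcm))))
  }
  if ("GLRLM" %in% classes) {
    nm <- feature_names_105()
    nm <- sub("^GLRLM__", "", nm[grepl("^GLRLM__", nm)])
    acc <- 0
    for (r in seq_len(nrow(dirs))) {
      cnt <- runlength_counts(G, dirs[r, ], Ng, lin_idx)
      acc <- acc + rl_features_one(cnt, Np)
    }
    out <- c(out, stats::setNames(acc / nrow(dirs), paste0("GLRLM__", nm)))
  }
  if ("GLSZM" %in% classes) {
    nm <- feature_names_105()
    nm <- sub("^GLSZM__", "", nm[grepl("^GLSZM__", nm)])
    zt <- zone_table(G, Ng)
    counts <- matrix(0, Ng, max(zt$size))
    t <- tabulate((zt$gray - 1L) * max(zt$size) + zt$size,
                  nbins = Ng * max(zt$size))
    counts <- matrix(t, Ng, max(zt$size), byrow = TRUE)
    out <- c(out, stats::setNames(rl_features_one(counts, Np),
                                  paste0("GLSZM__", nm)))
  }
  if ("GLDM" %in% classes || "NGTDM" %in% classes) {
    offs <- offsets26()
    dep <- array(0L, d)
    nb_sum <- array(0, d)
    nb_cnt <- array(0L, d)
    for (r in seq_len(nrow(offs))) {
      gn <- arr_shift_fill(G, offs[r, ])
      okn <- !is.na(gn)
      if ("GLDM" %in% classes)
        dep <- dep + (!is.na(G) & okn & gn == G)
      if ("NGTDM" %in% classes) {
        add <- gn; add[!okn] <- 0
        nb_sum <- nb_sum + add
        nb_cnt <- nb_cnt + okn
      }
    }
    if ("GLDM" %in% classes) {
      inm <- !is.na(G)
      g <- G[inm]; dj <- dep[inm] + 1L
      maxd <- max(dj)
      cnt <- matrix(tabulate((g - 1L) * maxd + dj, nbins = Ng * maxd),
                    Ng, maxd, byrow = TRUE)
      gl <- gldm_features(cnt)
      out <- c(out, stats::setNames(gl, paste0("GLDM__", names(gl))))
    }
    if ("NGTDM" %in% classes) {
      inm <- !is.na(G) & nb_cnt > 0
      avg <- nb_sum[inm] / nb_cnt[inm]
      g <- G[inm]
      s <- as.vector(tapply(abs(g - avg), factor(g, levels = 1:Ng), sum))
      s[is.na(s)] <- 0
      ni <- tabulate(g, nbins = Ng)
      ng <- ngtdm_features(s, ni)
      out <- c(out, stats::setNames(ng, paste0("NGTDM__", names(ng))))
    }
  }
  out
}

gldm_features <- function(counts) {
  i <- row(counts); j <- col(counts)
  Nz <- sum(counts)
  p <- counts / Nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pp <- p[p > 0]
  c(SmallDependenceEmphasis = sum(counts / j^2) / Nz,
    LargeDependenceEmphasis = sum(counts * j^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(counts)^2) / Nz,
    DependenceNonUniformity = sum(colSums(counts)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(counts)^2) / Nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    DependenceVariance = sum((j - mu_j)^2 * p),
    DependenceEntropy = -sum(pp * log2(pp)),
    LowGrayLevelEmphasis = sum(counts / i^2) / Nz,
    HighGrayLevelEmphasis = sum(counts * i^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(counts / (i^2 * j^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(counts * i^2 / j^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(counts * j^2 / i^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(counts * i^2 * j^2) / Nz)
}

ngtdm_features <- function(s, ni) {
  N <- sum(ni)
  pi_ <- ni / N
  lv <- which(ni > 0)
  Ngp <- length(lv)
  eps <- .Machine$double.eps
  coarse <- 1 / max(sum(pi_ * s), eps)
  coarse <- min(coarse, 1e6)
  if (Ngp > 1) {
    ij <- expand.grid(i = lv, j = lv)
    con <- sum(pi_[ij$i] * pi_[ij$j] * (ij$i - ij$j)^2) /
      (Ngp * (Ngp - 1)) * sum(s) / N
    busy_den <- sum(abs(ij$i * pi_[ij$i] - ij$j * pi_[ij$j]))
    busy <- if (busy_den > 0) sum(pi_ * s) / busy_den else 0
    cplx <- sum(abs(ij$i - ij$j) *
                  (pi_[ij$i] * s[ij$i] + pi_[ij$j] * s[ij$j]) /
                  (pi_[ij$i] + pi_[ij$j])) / N
    stren_num <- sum((pi_[ij$i] + pi_[ij$j]) * (ij$i - ij$j)^2)
    stren <- if (sum(s) > 0) stren_num / sum(s) else 0
  } else { con <- 0; busy <- 0; cplx <- 0; stren <- 0 }
  c(Coarseness = coarse, Contrast = con, Busyness = busy,
    Complexity = cplx, Strength = stren)
}

## ---- driver ----------------------------------------------------------------

#' Extract the standardized feature vector from one (matrix, ROI) pair
#'
#' @param matrix a `volume_grid` (CT, BED or interaction matrix).
#' @param roi `roi_mask` aligned with `matrix`.
#' @param config a [feature_config()]; defaults to fixed 32-bin count
#'   discretisation with all seven classes (105 features).
#' @return named numeric vector (`<class>__<feature>`). For an empty ROI,
#'   a vector of NA with attribute `flag = "empty_roi"`; for a 1-voxel ROI
#'   the texture entries are NA with `flag = "too_small"`. Deterministic
#'   given `config`.
#' @export
extract_features <- function(matrix, roi, config = feature_config()) {
  stopifnot(inherits(matrix, "volume_grid"), inherits(roi, "roi_mask"))
  stop_if_misaligned(matrix, roi, "matrix and roi")
  nm <- feature_names_105()
  nm <- nm[sub("__.*", "", nm) %in% config$classes]
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  n_in <- mask_count(roi)
  if (n_in == 0L) {
    attr(out, "flag") <- "empty_roi"
    return(out)
  }
  ci <- crop_indices(roi$values, roi$spacing, 0)
  mv <- roi$values[ci$lo[1]:ci$hi[1], ci$lo[2]:ci$hi[2], ci$lo[3]:ci$hi[3],
                   drop = FALSE]
  xv <- matrix$values[ci$lo[1]:ci$hi[1], ci$lo[2]:ci$hi[2],
                      ci$lo[3]:ci$hi[3], drop = FALSE]
  sp <- roi$spacing
  inmask <- mv > 0
  x <- xv[inmask]
  vals <- c()
  if ("Shape" %in% config$classes) {
    sh <- shape_features(mv, sp)
    vals <- c(vals, stats::setNames(sh, paste0("Shape__", names(sh))))
  }
  g <- discretize_gray(x, config)
  Ng <- max(g)
  if ("FirstOrder" %in% config$classes) {
    fo <- firstorder_features(x, g, prod(sp))
    vals <- c(vals, stats::setNames(fo, paste0("FirstOrder__", names(fo))))
  }
  tex_classes <- intersect(config$classes,
                           c("GLCM", "GLRLM", "GLSZM", "GLDM", "NGTDM"))
  flag <- NULL
  if (length(tex_classes)) {
    if (n_in >= 2L) {
      G <- array(NA_real_, dim(xv))
      G[inmask] <- g
      vals <- c(vals, texture_features(G, Ng, tex_classes))
    } else flag <- "too_small"
  }
  out[names(vals)] <- vals
  if (!is.null(flag)) attr(out, "flag") <- flag
  out
}

model_kind_matrices <- function(model_kind) {
  switch(model_kind,
         CT = "CT",
         BED = "BED",
         CT_BED = c("CT", "BED"),
         COMPOSITE = c("CT", "BED", "ENTROPY", "JSD", "MULTIPLY",
                       "SPEARMAN", "WASSERSTEIN"),
         stop(sprintf("unknown model kind '%s'", model_kind)))
}

#' Compute the per-case matrix set needed for a model kind
#'
#' @param case preprocessed `study_case`.
#' @param matrices character vector of matrix names.
#' @param n_bins interaction histogram bins.
#' @return named list of `volume_grid`s.
#' @export
case_matrices <- function(case, matrices, n_bins = 8L) {
  out <- list()
  if ("CT" %in% matrices) out$CT <- case$ct
  need_bed <- any(matrices != "CT")
  if (need_bed) {
    bed <- compute_bed(case$dose, case$n_fractions, alpha_beta_map(case$ptv))
    if ("BED" %in% matrices) out$BED <- bed
    im <- intersect(matrices, interaction_metrics)
    if (length(im))
      out <- c(out, compute_interactions(case$ct, bed, im, n_bins = n_bins))
  }
  out[matrices]
}

#' Assemble a cases x features table for one model configuration
#'
#' Feature columns are named `<matrix>__<roi>__<class>__<feature>`. With
#' the default (all-class) config the column counts are 420 (CT or BED),
#' 840 (CT_BED) and 2940 (COMPOSITE): 105 features x 4 ROIs x the model's
#' matrices. Rows are ordered by case id; cells of empty ROIs are NA and
#' the affected (case, ROI) pairs are listed in the `exclusions` attribute.
#'
#' @param cases list of preprocessed `study_case` objects.
#' @param model_kind `"CT"`, `"BED"`, `"CT_BED"` or `"COMPOSITE"`.
#' @param classes feature classes to extract (default all seven).
#' @param n_bins interaction histogram bins.
#' @param precomputed optional list (by case id) of named matrix lists, to
#'   reuse matrices across model kinds.
#' @return numeric matrix of class `feature_table` with attributes
#'   `model_kind` and `exclusions`.
#' @export
build_feature_table <- function(cases, model_kind, classes = feature_classes,
                                n_bins = 8L, precomputed = NULL) {
  mats <- model_kind_matrices(model_kind)
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  ord <- order(ids)
  cases <- cases[ord]; ids <- ids[ord]
  rows <- vector("list", length(cases))
  exclusions <- character(0)
  colnames_full <- NULL
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    vols <- if (!is.null(precomputed) && !is.null(precomputed[[cs$case_id]]))
      precomputed[[cs$case_id]][mats]
    else case_matrices(cs, mats, n_bins = n_bins)
    if (any(vapply(vols, is.null, logical(1))))
      stop(sprintf("case %s is missing a required matrix", cs$case_id))
    rois <- build_rois(cs)
    rest_classes <- setdiff(classes, "Shape")
    # shape depends only on the mask: compute it once per ROI, not per matrix
    shape_vecs <- if ("Shape" %in% classes)
      lapply(rois, function(r)
        extract_features(vols[[mats[1]]], r, feature_config(classes = "Shape")))
    else NULL
    vecs <- list()
    for (m in mats) {
      for (rn in names(rois)) {
        if (length(rest_classes)) {
          rest <- extract_features(vols[[m]], rois[[rn]],
                                   default_feature_config(m, rest_classes))
          fv <- c(shape_vecs[[rn]], rest)   # NULL shape drops out
          flag <- attr(rest, "flag")
        } else {
          fv <- shape_vecs[[rn]]
          flag <- attr(fv, "flag")
        }
        if (!is.null(flag))
          exclusions <- c(exclusions,
                          sprintf("%s:%s:%s=%s", cs$case_id, m, rn, flag))
        names(fv) <- paste0(m, "__", rn, "__", names(fv))
        vecs[[paste(m, rn, sep = "__")]] <- fv
      }
    }
    row <- unlist(vecs, use.names = TRUE)
    names(row) <- sub("^[^.]*\\.", "", names(row))  # strip list-name prefix
    if (is.null(colnames_full)) colnames_full <- names(row)
    rows[[ci]] <- row[colnames_full]
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- ids
  colnames(tab) <- colnames_full
  if (anyDuplicated(colnames_full)) stop("duplicated feature column names")
  structure(tab, model_kind = model_kind, exclusions = unique(exclusions),
            class = c("feature_table", class(tab)))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table %s: %d cases x %d features>\n",
              attr(x, "model_kind"), nrow(x), ncol(x)))
  invisible(x)
}
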
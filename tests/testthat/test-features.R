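test_that("the standardized vector has 105 features: 14 shape + 91 first-order/texture", {
  nm <- feature_names_105()
  expect_length(nm, 105)
  cls <- table(sub("__.*", "", nm))
  expect_equal(unname(cls["Shape"]), 14L)
  expect_equal(sum(cls) - cls[["Shape"]], 91)
  expect_equal(as.vector(cls[c("FirstOrder", "GLCM", "GLRLM", "GLSZM", "GLDM",
                               "NGTDM")]), c(18L, 22L, 16L, 16L, 14L, 5L))
  expect_false(anyDuplicated(nm) > 0)
  # shipped feature list agrees with the code
  j <- jsonlite::read_json(system.file("extdata", "feature_list_v1.json",
                                       package = "dosimix"))
  expect_equal(j$total, 105L)
})

test_that("extraction is deterministic and shape depends only on the mask", {
  v1 <- noise_volume(c(14, 14, 8), seed = 1, mean = -700, sd = 80)
  v2 <- noise_volume(c(14, 14, 8), seed = 2, mean = 40, sd = 400)
  m <- box_mask(c(14, 14, 8), c(4, 4, 2), c(11, 11, 7))
  f1 <- extract_features(v1, m)
  expect_identical(f1, extract_features(v1, m))
  f2 <- extract_features(v2, m)
  sh <- grepl("^Shape__", names(f1))
  expect_identical(f1[sh], f2[sh])
  expect_false(identical(f1[!sh], f2[!sh]))
  expect_length(f1, 105)
  expect_equal(sum(is.na(f1)), 0)
})

test_that("first-order statistics match direct arithmetic on a hand-built ROI", {
  dims <- c(4, 4, 2)
  v <- const_volume(0, dims, spacing = c(1, 1, 2))
  m <- v; m$values[] <- 0
  vals <- c(2, 4, 4, 10)
  v$values[1, 1, 1] <- 2; v$values[2, 1, 1] <- 4
  v$values[3, 1, 1] <- 4; v$values[4, 1, 1] <- 10
  m$values[1:4, 1, 1] <- 1
  roi <- roi_mask(m$values, v$spacing)
  fv <- extract_features(v, roi, feature_config(classes = "FirstOrder"))
  expect_equal(unname(fv["FirstOrder__Mean"]), mean(vals))
  expect_equal(unname(fv["FirstOrder__Minimum"]), 2)
  expect_equal(unname(fv["FirstOrder__Maximum"]), 10)
  expect_equal(unname(fv["FirstOrder__Median"]), 4)
  expect_equal(unname(fv["FirstOrder__Energy"]), sum(vals^2))
  expect_equal(unname(fv["FirstOrder__TotalEnergy"]), 2 * sum(vals^2))
  expect_equal(unname(fv["FirstOrder__Variance"]),
               mean((vals - mean(vals))^2))
  expect_equal(unname(fv["FirstOrder__Range"]), 8)
  expect_equal(unname(fv["FirstOrder__RootMeanSquared"]),
               sqrt(mean(vals^2)))
})

test_that("a constant matrix yields zero variance and the constant mean", {
  v <- const_volume(7.5, c(8, 8, 4))
  m <- box_mask(c(8, 8, 4), c(2, 2, 1), c(7, 7, 4))
  fv <- extract_features(v, m)
  expect_equal(unname(fv["FirstOrder__Variance"]), 0)
  expect_equal(unname(fv["FirstOrder__Mean"]), 7.5)
  expect_equal(unname(fv["FirstOrder__Entropy"]), 0)
  expect_equal(unname(fv["FirstOrder__Uniformity"]), 1)
})

test_that("shape descriptors match closed forms on a box mask", {
  m <- box_mask(c(12, 12, 8), c(3, 3, 2), c(6, 5, 4), spacing = c(1, 1, 2))
  # 4 x 3 x 3 voxels at 1 x 1 x 2 mm: a 4 x 3 x 6 mm cuboid of voxel centres
  fv <- extract_features(const_volume(1, c(12, 12, 8)), m,
                         feature_config(classes = "Shape"))
  expect_equal(unname(fv["Shape__VoxelCount"]), 36)
  expect_equal(unname(fv["Shape__VoxelVolume"]), 36 * 2)
  a <- 4; b <- 3; cz <- 3   # voxel counts per axis
  expect_equal(unname(fv["Shape__SurfaceArea"]),
               2 * (a * b * 1 * 1) + 2 * (a * cz * 1 * 2) + 2 * (b * cz * 1 * 2))
  # centre-to-centre diagonal: (3, 2, 4 mm)
  expect_equal(unname(fv["Shape__Maximum3DDiameter"]),
               sqrt(3^2 + 2^2 + 4^2))
  expect_equal(unname(fv["Shape__Maximum2DDiameterSlice"]),
               sqrt(3^2 + 2^2))
})

test_that("gray-level co-occurrence features equal a brute-force oracle", {
  set.seed(33)
  d <- c(4, 4, 3)
  v <- volume_grid(array(sample(1:4, prod(d), TRUE) * 25 - 13, d), c(1, 1, 1))
  m <- box_mask(d, c(1, 1, 1), d, spacing = c(1, 1, 1))
  fv <- extract_features(v, m, feature_config("width", bin_width = 25,
                                              classes = "GLCM"))
  g <- floor(v$values / 25) - floor(min(v$values) / 25) + 1
  Ng <- max(g)
  offs <- dosimix:::offsets13()
  contr <- jent <- maxp <- numeric(13)
  for (r in 1:13) {
    P <- matrix(0, Ng, Ng)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      t <- c(i, j, k) + offs[r, ]
      if (all(t >= 1 & t <= d)) {
        a <- g[i, j, k]; b <- g[t[1], t[2], t[3]]
        P[a, b] <- P[a, b] + 1; P[b, a] <- P[b, a] + 1
      }
    }
    P <- P / sum(P)
    contr[r] <- sum(outer(1:Ng, 1:Ng, function(x, y) (x - y)^2) * P)
    pp <- P[P > 0]; jent[r] <- -sum(pp * log2(pp))
    maxp[r] <- max(P)
  }
  expect_equal(unname(fv["GLCM__Contrast"]), mean(contr))
  expect_equal(unname(fv["GLCM__JointEntropy"]), mean(jent))
  expect_equal(unname(fv["GLCM__MaximumProbability"]), mean(maxp))
})

test_that("run-length features equal a direction-by-direction rle oracle", {
  set.seed(44)
  d <- c(5, 4, 3)
  v <- volume_grid(array(sample(1:3, prod(d), TRUE), d), c(1, 1, 1))
  m <- box_mask(d, c(1, 1, 1), d, spacing = c(1, 1, 1))
  fv <- extract_features(v, m, feature_config("count", n_bins = 3,
                                              classes = "GLRLM"))
  g <- dosimix:::discretize_gray(as.vector(v$values),
                                 feature_config("count", n_bins = 3))
  G <- array(g, d)
  # oracle for the x direction: rle along each (y, z) line
  sre_x <- local({
    runs <- NULL
    for (j in 1:d[2]) for (k in 1:d[3]) {
      r <- rle(G[, j, k])
      runs <- rbind(runs, cbind(r$values, r$lengths))
    }
    sum(1 / runs[, 2]^2) / nrow(runs)
  })
  lin <- array(seq_len(prod(d)), d)
  cnt <- dosimix:::runlength_counts(G * NA^0, c(1, 0, 0), 3, lin)
  expect_equal(sum(cnt / col(cnt)^2) / sum(cnt), sre_x)
  expect_true(is.finite(fv["GLRLM__ShortRunEmphasis"]))
  expect_true(fv["GLRLM__RunPercentage"] <= 1)
})

test_that("zone statistics match hand-counted connected components", {
  G <- array(NA_real_, c(4, 4, 1))
  G[1, 1, 1] <- 1; G[1, 2, 1] <- 1; G[2, 2, 1] <- 1
  G[4, 4, 1] <- 1
  G[3, 1, 1] <- 2; G[4, 1, 1] <- 2
  zt <- dosimix:::zone_table(G, 2)
  zt <- zt[order(zt$gray, zt$size), ]
  expect_equal(zt$gray, c(1, 1, 2))
  expect_equal(zt$size, c(1, 3, 2))
})

test_that("dependence counts match a brute-force neighbour scan", {
  set.seed(55)
  d <- c(4, 4, 3)
  g <- array(sample(1:3, prod(d), TRUE), d)
  G <- g; mode(G) <- "double"
  offs <- dosimix:::offsets26()
  dep_brute <- array(0, d)
  for (i in 1:4) for (j in 1:4) for (k in 1:3) for (r in 1:26) {
    t <- c(i, j, k) + offs[r, ]
    if (all(t >= 1 & t <= d) && g[t[1], t[2], t[3]] == g[i, j, k])
      dep_brute[i, j, k] <- dep_brute[i, j, k] + 1
  }
  v <- volume_grid(G * 10, c(1, 1, 1))
  m <- box_mask(d, c(1, 1, 1), d, spacing = c(1, 1, 1))
  fv <- extract_features(v, m, feature_config("count", n_bins = 3,
                                              classes = "GLDM"))
  # LargeDependenceEmphasis from the brute-force dependence histogram
  jj <- as.vector(dep_brute) + 1
  expect_equal(unname(fv["GLDM__LargeDependenceEmphasis"]), mean(jj^2))
})

test_that("empty and one-voxel ROIs are flagged as the policy requires", {
  v <- noise_volume(c(6, 6, 4), seed = 9)
  m0 <- box_mask(c(6, 6, 4), c(1, 1, 1), c(1, 1, 1)); m0$values[] <- 0
  f0 <- extract_features(v, m0)
  expect_equal(attr(f0, "flag"), "empty_roi")
  expect_true(all(is.na(f0)))
  m1 <- box_mask(c(6, 6, 4), c(3, 3, 2), c(3, 3, 2))
  f1 <- extract_features(v, m1)
  expect_equal(attr(f1, "flag"), "too_small")
  expect_false(is.na(f1["FirstOrder__Mean"]))
  expect_true(all(is.na(f1[grepl("^GLCM__", names(f1))])))
})

test_that("feature tables carry the model-specific column counts", {
  cases <- lapply(1:2, function(s) tiny_case(dims = c(14, 14, 10), seed = s))
  comp <- build_feature_table(cases, "COMPOSITE")
  expect_equal(ncol(comp), 2940)
  expect_equal(nrow(comp), 2)
  expect_equal(ncol(subset_feature_table(comp, "CT")), 420)
  expect_equal(ncol(subset_feature_table(comp, "BED")), 420)
  expect_equal(ncol(subset_feature_table(comp, "CT_BED")), 840)
  expect_false(anyDuplicated(colnames(comp)) > 0)
  expect_equal(rownames(comp), sort(vapply(cases, function(x) x$case_id,
                                           character(1))))
  ctonly <- build_feature_table(cases, "CT")
  expect_equal(ncol(ctonly), 420)
  expect_equal(unname(ctonly[, colnames(subset_feature_table(comp, "CT"))]),
               unname(subset_feature_table(comp, "CT")[, ]))
})

test_that("a case with an empty ISO50 keeps its row with flagged cells", {
  cs <- tiny_case(dims = c(14, 14, 10), seed = 3)
  cs$dose$values[] <- 0.1 * cs$prescription_dose  # nothing reaches 50%
  cs$dose$values[cs$ptv$values > 0] <- cs$prescription_dose
  # ISO50 = dose >= 0.5 presc outside PTV -> empty
  tab <- build_feature_table(list(cs), "CT", classes = "FirstOrder")
  iso_cols <- grepl("__ISO50__", colnames(tab))
  expect_true(all(is.na(tab[1, iso_cols])))
  expect_false(anyNA(tab[1, !iso_cols]))
  expect_match(attr(tab, "exclusions"), "ISO50", all = FALSE)
})
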
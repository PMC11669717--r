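make_pair <- function(ct_vals, bed_vals) {
  d <- c(3, 3, 3)
  extract_patch_pair(volume_grid(array(ct_vals, d), c(1, 1, 1)),
                     volume_grid(array(bed_vals, d), c(1, 1, 1)),
                     c(2, 2, 2))
}

test_that("patch extraction returns literal neighbours inside and replicates edges", {
  v <- noise_volume(c(5, 5, 5), seed = 1)
  b <- noise_volume(c(5, 5, 5), seed = 2)
  p <- extract_patch_pair(v, b, c(3, 3, 3))
  expect_equal(p$ct_patch, as.vector(v$values[2:4, 2:4, 2:4]))
  expect_equal(p$bed_patch, as.vector(b$values[2:4, 2:4, 2:4]))
  corner <- extract_patch_pair(v, b, c(1, 1, 1))
  expect_equal(length(corner$ct_patch), 27)
  expect_equal(sort(unique(corner$ct_patch)),
               sort(unique(as.vector(v$values[1:2, 1:2, 1:2]))))
  cp <- extract_patch_pair(const_volume(4, c(5, 5, 5)), v, c(1, 5, 3))
  expect_all_equal(cp$ct_patch, 4)
  expect_error(extract_patch_pair(v, b, c(0, 1, 1)), "outside")
})

test_that("patch Spearman matches the hand rank formula and its conventions", {
  x <- 1:27
  expect_equal(patch_spearman(make_pair(x, x)), 1)
  expect_equal(patch_spearman(make_pair(x, -x)), -1)
  perm <- dosimix:::with_seed(42, sample(27))
  d2 <- sum((rank(x) - rank(perm))^2)
  expect_equal(patch_spearman(make_pair(x, perm)),
               1 - 6 * d2 / (27 * (27^2 - 1)))
  expect_equal(patch_spearman(make_pair(rep(1, 27), x)), 0)
})

test_that("patch histograms are normalised probability vectors with the degenerate rule", {
  h <- patch_histograms(make_pair(rep(5, 27), 1:27))
  expect_equal(h$ct, c(1, rep(0, 7)))
  expect_equal(sum(h$bed), 1)
  h2 <- patch_histograms(make_pair(stats::runif(27), stats::runif(27)))
  expect_equal(sum(h2$ct), 1)
  expect_equal(sum(h2$bed), 1)
  expect_error(patch_histograms(make_pair(1:27, 1:27), n_bins = 1), "at least 2")
})

test_that("joint patch entropy hits closed forms and the sample-size bound", {
  expect_equal(patch_entropy(make_pair(rep(1, 27), rep(2, 27))), 0)
  # 27 pairs spread over 3 equally occupied joint cells -> log2(3)
  ct <- rep(c(0, 0.5, 1), each = 9)
  bed <- rep(c(0, 1, 0.5), each = 9)
  expect_equal(patch_entropy(make_pair(ct, bed)), log2(3))
  rnd <- make_pair(stats::runif(27), stats::runif(27))
  expect_lte(patch_entropy(rnd), log2(27))
  expect_gte(patch_entropy(rnd), 0)
})

test_that("patch JSD matches a term-by-term hand computation and its bounds", {
  expect_equal(patch_jsd(make_pair(1:27, 1:27)), 0)
  # reversing a ramp leaves the value multiset (hence the histogram) alone
  pj <- make_pair(seq(0, 26), -seq(0, 26))
  expect_equal(patch_jsd(pj), 0)
  # hand evaluation on fixed histograms via the defining formula
  p <- make_pair(rep(c(0, 1), c(20, 7)), rep(c(0, 1), c(9, 18)))
  h <- patch_histograms(p)
  M <- (h$ct + h$bed) / 2
  kl <- function(a) sum(ifelse(a > 0, a * log2(a / M), 0))
  expect_equal(patch_jsd(p), 0.5 * kl(h$ct) + 0.5 * kl(h$bed))
  expect_gte(patch_jsd(p), 0); expect_lte(patch_jsd(p), 1)
  # disjoint-support histograms attain the base-2 maximum of 1
  expect_equal(dosimix:::jsd_vec(c(1, rep(0, 7)), c(rep(0, 7), 1)), 1)
})

test_that("patch Wasserstein matches the sort-and-average oracle and W1 properties", {
  expect_equal(patch_wasserstein(make_pair(1:27, 1:27)), 0)
  a <- dosimix:::with_seed(7, stats::runif(27, 0, 0.5))
  p <- make_pair(a, a + 0.3)
  expect_equal(patch_wasserstein(p, normalize = FALSE), 0.3)  # translation
  b <- dosimix:::with_seed(8, stats::rnorm(27))
  q <- make_pair(a, b)
  n1 <- dosimix:::minmax01(a); n2 <- dosimix:::minmax01(b)
  expect_equal(patch_wasserstein(q), mean(abs(sort(n1) - sort(n2))))
  expect_gte(patch_wasserstein(q), 0)
})

test_that("pairwise multiplication is exact element-wise product", {
  v <- noise_volume(c(4, 4, 4), seed = 3)
  zero <- const_volume(0, c(4, 4, 4))
  expect_all_equal(pairwise_multiply(v, zero)$values, 0)
  one <- const_volume(1, c(4, 4, 4))
  expect_equal(pairwise_multiply(v, one)$values, v$values)
  a <- const_volume(-500, c(4, 4, 4)); b <- const_volume(100, c(4, 4, 4))
  expect_all_equal(pairwise_multiply(a, b)$values, -50000)
})

test_that("sliding-window engine equals per-voxel recomputation to 1e-10", {
  v <- noise_volume(c(6, 6, 6), seed = 21)
  b <- noise_volume(c(6, 6, 6), seed = 22)
  for (m in interaction_metrics) {
    iv <- interaction_volume(v, b, m)
    ref <- array(0, c(6, 6, 6))
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      p <- extract_patch_pair(v, b, c(i, j, k))
      ref[i, j, k] <- switch(m,
        ENTROPY = patch_entropy(p), JSD = patch_jsd(p),
        SPEARMAN = patch_spearman(p), WASSERSTEIN = patch_wasserstein(p),
        MULTIPLY = p$ct_patch[14] * p$bed_patch[14])
    }
    expect_all_equal(iv$values, ref, tol = 1e-10)
  }
})

test_that("interaction metrics respect their ranges, symmetries and invariances", {
  v <- noise_volume(c(6, 6, 6), seed = 31)
  b <- noise_volume(c(6, 6, 6), seed = 32)
  expect_true(all(abs(interaction_volume(v, b, "SPEARMAN")$values) <= 1))
  jsd <- interaction_volume(v, b, "JSD")$values
  expect_true(all(jsd >= 0 & jsd <= 1))
  expect_true(all(interaction_volume(v, b, "ENTROPY")$values >= 0))
  expect_true(all(interaction_volume(v, b, "WASSERSTEIN")$values >= 0))
  for (m in c("JSD", "WASSERSTEIN", "SPEARMAN", "MULTIPLY"))
    expect_all_equal(interaction_volume(v, b, m)$values,
                     interaction_volume(b, v, m)$values)
  # Spearman is invariant under strictly increasing transforms
  mono <- v; mono$values <- exp(v$values)
  sp <- interaction_volume(v, mono, "SPEARMAN")$values
  expect_all_equal(sp, 1)
  sp2 <- interaction_volume(v, b, "SPEARMAN")$values
  b2 <- b; b2$values <- b$values^3
  expect_all_equal(interaction_volume(v, b2, "SPEARMAN")$values, sp2)
  # MULTIPLY path consistency
  expect_equal(interaction_volume(v, b, "MULTIPLY")$values,
               pairwise_multiply(v, b)$values)
  expect_error(interaction_volume(v, b, "MUTUAL_INFO"), "unknown")
})
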
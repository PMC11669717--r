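# shared fixture builders: everything is generated in code at test time

const_volume <- function(value, dims = c(6, 6, 6), spacing = c(1, 1, 2)) {
  volume_grid(array(value, dims), spacing)
}

noise_volume <- function(dims = c(6, 6, 6), spacing = c(1, 1, 2), seed = 1,
                         mean = 0, sd = 1) {
  vals <- dosimix:::with_seed(seed, array(stats::rnorm(prod(dims), mean, sd),
                                          dims))
  volume_grid(vals, spacing)
}

box_mask <- function(dims, lo, hi, spacing = c(1, 1, 2), label = "ROI") {
  m <- array(0, dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  roi_mask(m, spacing, label = label)
}

# a small fully-synthetic case on a given grid
tiny_case <- function(dims = c(16, 16, 10), spacing = c(1, 1, 2), seed = 1,
                      prescription = 50, n_fx = 5) {
  ct <- noise_volume(dims, spacing, seed = seed, mean = -750, sd = 60)
  gtv <- box_mask(dims, pmax(dims %/% 2 - 1, 1), dims %/% 2 + 1, spacing,
                  label = "GTV")
  ct$values[gtv$values > 0] <- dosimix:::with_seed(
    seed + 1, stats::rnorm(mask_count(gtv), 0, 30))
  ptv <- box_mask(dims, pmax(dims %/% 2 - 2, 1),
                  pmin(dims %/% 2 + 2, dims), spacing, label = "PTV")
  dm <- distance_map_mm(ptv)
  dose <- volume_grid(prescription * exp(-dm / 6), spacing)
  study_case(sprintf("tiny%03d", seed), ct, dose, gtv, ptv, prescription,
             n_fx, outcome_record(FALSE, 12))
}

expect_all_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
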
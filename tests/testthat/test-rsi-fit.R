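test_that("median-b0 normalization follows the definition", {
  # uniform b=0 volume: every b=0 voxel becomes exactly 1
  s <- tiny_series(matrix(400, 1, 4), fill = 400)
  mask <- first_voxels_mask(5)
  norm <- normalize_by_median_b0(s, mask)
  expect_true(norm$normalized)
  expect_true(all(norm$signal[, , , 1] == 1))

  # printed 3-voxel example: b=0 values {2, 4, 6} -> divisor 4
  rows <- cbind(c(2, 4, 6), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  s3 <- tiny_series(rows, fill = 4)
  norm3 <- normalize_by_median_b0(s3, first_voxels_mask(3))
  expect_equal(norm3$signal[, , , 1][1:3], c(0.5, 1.0, 1.5))

  # idempotence at the fixed point
  again <- normalize_by_median_b0(norm3, first_voxels_mask(3))
  expect_equal(again$signal, norm3$signal, tolerance = 1e-12)

  # degenerate inputs
  expect_error(normalize_by_median_b0(s, array(FALSE, c(4, 4, 3))), "empty")
  s0 <- tiny_series(matrix(0, 1, 4), fill = 0)
  expect_error(normalize_by_median_b0(s0, mask), "not positive")
})

test_that("decay design matrix has the compartmental structure", {
  A <- decay_design_matrix(c(0, 500, 1000, 2000))
  expect_equal(dim(A), c(4L, 4L))
  expect_equal(unname(A[1, ]), rep(1, 4))                 # b = 0 row
  expect_equal(A["b1000", "hindered"], exp(-1.8), tolerance = 1e-12)
  expect_identical(unname(A[2:4, "flow"]), rep(0, 3))     # flow convention
})

test_that("noiseless compartment signals are recovered exactly", {
  p <- acquisition_protocol()
  mask <- first_voxels_mask(3)
  truths <- rbind(c(1, 0, 0, 0),
                  c(0, 0, 0, 0),
                  c(0.3, 0.5, 0.15, 0.05))
  A <- decay_design_matrix(p$b_values)
  s <- tiny_series(truths %*% t(A), fill = 1, normalized = TRUE)
  maps <- fit_compartments(s, mask)
  for (i in 1:3) {
    expect_equal(unname(maps$c[, , , ][cbind(i, 1, 1, 1:4)]), truths[i, ],
                 tolerance = 1e-8)
    expect_lt(maps$residual_rms[i], 1e-8)
  }
  # restriction score is the C1 map voxelwise
  rs <- compute_rsirs(maps)
  expect_identical(rs$value, maps$c[, , , 1])
  expect_equal(rs$value[3], 0.3, tolerance = 1e-8)

  # out-of-mask voxels are sentinel no-data
  expect_true(all(is.na(rs$value[!mask])))

  # fitting an unnormalized series is a contract violation
  raw <- tiny_series(truths %*% t(A))
  expect_error(fit_compartments(raw, mask), "normalized")
})

test_that("constrained fit matches the Lawson-Hanson oracle on random voxels", {
  p <- acquisition_protocol()
  A <- decay_design_matrix(p$b_values)
  set.seed(61)
  n <- 120
  # noisy signals, some from negative-coefficient-tempting regimes
  S <- matrix(abs(rnorm(4 * n, mean = 0.3, sd = 0.3)), 4, n)
  mask <- array(FALSE, c(n, 1, 1))
  mask[] <- TRUE
  arr <- array(t(S), c(n, 1, 1, 4))
  series <- dwi_series(arr, p$b_values, c(2.5, 2.5, 6), normalized = TRUE)
  maps <- fit_compartments(series, mask)
  for (i in seq_len(n)) {
    expected <- oracle_nnls(A, S[, i])
    got <- maps$c[i, 1, 1, ]
    expect_equal(unname(got), expected, tolerance = 1e-6)
  }
  # nonnegativity everywhere
  expect_true(all(maps$c[!is.na(maps$c)] >= 0))
})

test_that("fits are invariant to global signal scaling after normalization", {
  cfg <- cohort_config(n_patients = 1, seed = 8)
  pat <- simulate_patient(cfg, 3, "peripheral_zone", seed = 12)
  seg <- pat$segmentation
  scaled <- dwi_series(pat$dwi$signal * 7.3, pat$dwi$b_values,
                       pat$dwi$voxel_size_mm)
  m1 <- fit_compartments(normalize_by_median_b0(pat$dwi, seg$prostate),
                         seg$prostate)
  m2 <- fit_compartments(normalize_by_median_b0(scaled, seg$prostate),
                         seg$prostate)
  expect_equal(m1$c, m2$c, tolerance = 1e-9)
})

test_that("restricted fraction is recovered under realistic noise", {
  # tumor-archetype voxels at b=0 SNR 20: small bias/variance in C1 and
  # strong rank agreement between truth and fit
  p <- acquisition_protocol()
  set.seed(77)
  n <- 1000
  c1_true <- runif(n, 0.2, 0.6)
  frac <- cbind(c1_true, 0.85 - c1_true, 0.10, 0.05)
  A <- decay_design_matrix(p$b_values)
  S <- frac %*% t(A)
  sigma <- 0.05
  S <- sqrt((S + rnorm(length(S), sd = sigma))^2 +
              matrix(rnorm(length(S), sd = sigma), nrow(S))^2)
  series <- dwi_series(array(S, c(n, 1, 1, 4)), p$b_values, c(2.5, 2.5, 6),
                       normalized = TRUE)
  mask <- array(TRUE, c(n, 1, 1))
  c1_hat <- fit_compartments(series, mask)$c[, 1, 1, 1]
  expect_lt(mean(abs(c1_hat - c1_true)), 0.05)
  expect_gt(cor(c1_hat, c1_true, method = "spearman"), 0.9)
})
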
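test_that("noiseless voxel signal follows the compartmental decay model", {
  p <- acquisition_protocol()

  # pure restricted compartment: exp(-b * 1e-4) at each b
  s <- simulate_voxel_signal(c(1, 0, 0, 0), p, noise_sigma = 0)
  expect_equal(s, exp(-c(0, 500, 1000, 2000) * 1e-4), tolerance = 1e-12)

  # zero fractions give zero signal; unit-sum fractions give exactly 1 at b=0
  expect_equal(simulate_voxel_signal(c(0, 0, 0, 0), p, 0), rep(0, 4))
  s2 <- simulate_voxel_signal(c(0.3, 0.5, 0.15, 0.05), p, 0)
  expect_identical(s2[1], 1.0)

  # flow contributes only at b = 0
  s3 <- simulate_voxel_signal(c(0, 0, 0, 1), p, 0)
  expect_equal(s3, c(1, 0, 0, 0))

  expect_error(simulate_voxel_signal(c(-0.1, 0.5, 0.3, 0.3), p, 0),
               "nonnegative")
  expect_error(simulate_voxel_signal(c(1, 0, 0, 0), p, -1), "nonnegative")
})

test_that("simulated Rician magnitudes match the analytic Rice mean", {
  p <- acquisition_protocol(b_values = c(0, 1000), directions_per_b = c(1, 1))
  sigma <- 0.05
  set.seed(11)
  for (fr in list(c(0.5, 0.3, 0.1, 0.05), c(0.02, 0.02, 0.01, 0))) {
    noiseless <- simulate_voxel_signal(fr, p, 0)
    draws <- replicate(2e4, simulate_voxel_signal(fr, p, sigma))
    for (j in 1:2) {
      expected <- rice_mean(noiseless[j], sigma)
      se <- sd(draws[j, ]) / sqrt(ncol(draws))
      expect_lt(abs(mean(draws[j, ]) - expected), 3 * se)
    }
  }
})

test_that("PI-RADS sampling matches the detection model", {
  # point mass
  m <- pirads_detection_model(data.frame(pirads = 1:5,
                                         n_negative = c(0, 0, 0, 0, 1),
                                         n_positive = c(0, 0, 0, 0, 1)))
  expect_true(all(sample_pirads(rep(TRUE, 50), m) == 5L))

  # Monte-Carlo frequencies against the analytic conditionals, and the
  # implied posterior P(csPCa | category 5) at the published prevalence
  m <- pirads_detection_model()
  set.seed(21)
  n <- 1e5
  pos <- sample_pirads(rep(TRUE, n), m)
  neg <- sample_pirads(rep(FALSE, n), m)
  expect_true(all(abs(tabulate(pos, 5) / n - m$positive) < 0.02))
  expect_true(all(abs(tabulate(neg, 5) / n - m$negative) < 0.02))

  prev <- 86 / 151
  n5_pos <- sum(pos == 5) / n * prev
  n5_neg <- sum(neg == 5) / n * (1 - prev)
  expect_equal(n5_pos / (n5_pos + n5_neg), 0.844, tolerance = 0.01)
})

test_that("cohort simulation is deterministic and respects its config", {
  cfg <- cohort_config(n_patients = 0)
  empty <- simulate_cohort(cfg)
  expect_identical(nrow(empty$truth), 0L)
  expect_length(empty$patients, 0)

  cfg <- cohort_config(n_patients = 12, seed = 303)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$patients[[3]]$dwi$signal, b$patients[[3]]$dwi$signal)

  # csPCa fraction over a larger truth-only draw stays within the binomial
  # 99% band of the configured grade-group mass on groups 2..5
  cfg200 <- cohort_config(n_patients = 200, seed = 7)
  tr <- simulate_cohort(cfg200, return_patients = FALSE)$truth
  p <- sum(cfg200$grade_group_probs[3:6])
  band <- qbinom(c(0.005, 0.995), 200, p)
  expect_gte(sum(tr$cspca), band[1])
  expect_lte(sum(tr$cspca), band[2])
})

test_that("synthetic patients have consistent labels and geometry", {
  cfg <- cohort_config(n_patients = 10, seed = 99)
  sim <- simulate_cohort(cfg)
  for (i in seq_len(10)) {
    pat <- sim$patients[[i]]
    seg <- pat$segmentation
    # zones partition the prostate
    expect_false(any(seg$peripheral_zone & seg$central_gland))
    expect_identical(seg$peripheral_zone | seg$central_gland, seg$prostate)
    # lesion iff grade group >= 1, and inside the prostate
    if (pat$truth$grade_group >= 1) {
      expect_gt(sum(pat$truth$lesion_mask), 0)
      expect_true(all(seg$prostate[pat$truth$lesion_mask]))
      zone_mask <- if (pat$truth$lesion_zone == "peripheral_zone") {
        seg$peripheral_zone
      } else {
        seg$central_gland
      }
      expect_true(all(zone_mask[pat$truth$lesion_mask]))
    } else {
      expect_identical(sum(pat$truth$lesion_mask), 0L)
    }
    expect_true(pat$pirads %in% 1:5)
  }
})

test_that("config validation rejects degenerate settings", {
  expect_error(cohort_config(grade_group_probs = rep(0.2, 6)), "sum to 1")
  expect_error(cohort_config(noise_sigma = -0.1), ">= 0")
  expect_error(cohort_config(grid_shape = c(4, 40, 14)), ">= 8")
  # grid too small to hold a lesion of the configured size
  cfg <- cohort_config(grid_shape = c(8, 8, 8), voxel_size_mm = c(1, 1, 1),
                       prostate_semi_axes_mm = c(2, 2, 2),
                       min_lesion_voxels = 50L)
  expect_error(simulate_patient(cfg, 2, "peripheral_zone", seed = 1),
               "too small")
})

test_that("NIfTI round trip preserves signals and masks", {
  cfg <- cohort_config(n_patients = 1, seed = 5)
  pat <- simulate_patient(cfg, 2, "peripheral_zone", seed = 42)
  dir <- withr::local_tempdir()
  paths <- write_patient_nifti(pat, dir, "p001")
  expect_true(all(file.exists(paths)))
  back <- read_dwi_nifti(paths[["dwi"]], paths[["bvals"]])
  expect_equal(back$signal, pat$dwi$signal, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$b_values, pat$dwi$b_values)
  mask <- read_mask_nifti(paths[["prostate"]])
  expect_identical(mask, pat$segmentation$prostate)
})
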
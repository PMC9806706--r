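test_that("midrank AUC handles separation, ties and ordinal scores", {
  expect_equal(auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  # brute force over the 4 pos/neg pairs: one win, two ties, one loss
  expect_equal(auc(c(1, 2, 1, 2), c(FALSE, TRUE, TRUE, FALSE)), 0.5)
  expect_equal(auc(rep(3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_error(auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("midrank AUC equals exhaustive pairwise counting, with complement symmetry", {
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(1:6, n, replace = TRUE) + # heavy ties
      ifelse(runif(n) < 0.5, 0, runif(n))
    expect_identical(auc(scores, labels), pairwise_auc(scores, labels))
    expect_equal(auc(scores, labels) + auc(-scores, labels), 1.0)
  }
})

test_that("midrank AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (rep in 1:10) {
    n <- 40
    labels <- runif(n) < 0.4
    labels[1:2] <- c(TRUE, FALSE)
    scores <- rnorm(n) + labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone and consistent with the AUC", {
  set.seed(17)
  labels <- runif(50) < 0.5
  labels[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(50) + labels
  rc <- roc_curve(scores, labels)
  expect_true(all(diff(rc$points$sensitivity) >= 0))
  expect_true(all(diff(rc$points$specificity) <= 0))
  expect_true(all(rc$points$sensitivity >= 0 & rc$points$sensitivity <= 1))
  expect_equal(rc$auc, auc(scores, labels))
})

test_that("bootstrap comparison handles identical, opposite and seeded runs", {
  set.seed(3)
  labels <- rep(c(TRUE, FALSE), each = 20)
  x <- rnorm(40) + labels

  same <- bootstrap_compare(x, x, labels, n_boot = 500, seed = 1)
  expect_equal(same$delta, 0)
  expect_equal(same$ci95, c(0, 0))
  expect_equal(same$p_two_sided, 1)

  # perfectly separating vs anti-separating: every resample has delta > 0,
  # so p sits at its floor
  sep <- as.numeric(labels)
  opp <- bootstrap_compare(sep, -sep, labels, n_boot = 2000, seed = 2)
  expect_lte(opp$p_two_sided, 0.001)
  expect_equal(opp$p_two_sided, 2 / 2001)

  # fixed seed reproduces the full object bit-identically
  y <- rnorm(40) + 0.5 * labels
  r1 <- bootstrap_compare(x, y, labels, n_boot = 400, seed = 7)
  r2 <- bootstrap_compare(x, y, labels, n_boot = 400, seed = 7)
  expect_identical(r1, r2)
  expect_warning(bootstrap_compare(x, y, labels, n_boot = 50, seed = 1),
                 "unstable")
})

test_that("stratified posteriors concatenate within-stratum discrimination", {
  set.seed(23)
  # single stratum: combined ranking equals the marker ranking
  n <- 30
  labels <- runif(n) < 0.5
  labels[1:2] <- c(TRUE, FALSE)
  marker <- rnorm(n) + labels
  one <- stratified_posteriors(marker, labels, rep(1, n))
  expect_identical(rank(one$combined_score), rank(marker))

  # constant marker in a stratum: flat posterior, AUC contribution 1/2
  flat <- stratified_posteriors(rep(2.5, n), labels, rep(1, n))
  expect_identical(length(unique(flat$posterior)), 1L)
  expect_equal(auc(flat$combined_score, labels), 0.5)

  # two strata, each conditionally informative: combined beats strata alone
  n2 <- 200
  strata <- rep(c(1, 2), each = n2 / 2)
  labels2 <- c(runif(n2 / 2) < 0.3, runif(n2 / 2) < 0.7)
  marker2 <- rnorm(n2, sd = 1) + labels2
  comb <- stratified_posteriors(marker2, labels2, strata)
  expect_gt(auc(comb$combined_score, labels2), auc(strata, labels2))
  # lexicographic contract: higher stratum always outranks lower
  expect_gt(min(comb$combined_score[strata == 2]),
            max(comb$combined_score[strata == 1]))

  # combined ROC equals brute-force pairwise counting on the combined score
  rc <- combined_roc(comb, labels2)
  expect_equal(rc$auc, pairwise_auc(comb$combined_score, labels2))
})

test_that("stratified posteriors fall back to ranks in degenerate strata", {
  # perfect separation inside the stratum would break the logistic fit
  marker <- c(1, 2, 3, 10, 11, 12, rnorm(20))
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, runif(20) < 0.5)
  labels[7:8] <- c(TRUE, FALSE)
  strata <- rep(c(1, 2), c(6, 20))
  fit <- stratified_posteriors(marker, labels, strata)
  expect_identical(fit$fits$method[1], "rank")
  # rank fallback preserves the within-stratum ROC
  in1 <- strata == 1
  expect_equal(auc(fit$combined_score[in1], labels[in1]),
               auc(marker[in1], labels[in1]))
  # tiny stratum (below min_per_class) also falls back
  small <- stratified_posteriors(rnorm(24), c(TRUE, rep(FALSE, 11), runif(12) < 0.5) ,
                                 rep(c(1, 2), each = 12))
  expect_identical(small$fits$method[1], "rank")
})

test_that("detection-rate table reproduces printed worked examples", {
  tbl <- detection_rate_table(pirads = c(rep(3, 27), rep(4, 55)),
                              cspca = c(rep(FALSE, 23), rep(TRUE, 4),
                                        rep(FALSE, 30), rep(TRUE, 25)))
  expect_equal(tbl$rate_percent[tbl$pirads == 3], 14.8)
  expect_equal(tbl$rate_percent[tbl$pirads == 4], 45.5)
  expect_identical(tbl$n_negative[tbl$pirads == 3], 23L)
  # empty and all-negative categories
  expect_true(is.na(tbl$rate_percent[tbl$pirads == 5]))
  tbl0 <- detection_rate_table(rep(2, 10), rep(FALSE, 10))
  expect_equal(tbl0$rate_percent[tbl0$pirads == 2], 0.0)
})
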
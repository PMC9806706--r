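#' Area under the ROC curve by midranks
#'
#' Mann-Whitney estimate: the probability that a random positive outranks a
#' random negative, with ties counted as half-wins. Identical for continuous
#' markers and ordinal scores (such as PI-RADS categories).
#'
#' @param scores Numeric vector (higher = more suspicious).
#' @param labels Logical (or 0/1) vector; `TRUE` = positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not contain NA")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute an AUC")
  r <- rank(scores)                               # midranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve of a marker
#'
#' Sensitivity/specificity at every distinct threshold, plus the midrank AUC.
#'
#' @inheritParams auc
#' @param score_name Label stored with the curve.
#' @return Object of class `roc_curve`: data frame `points` with columns
#'   `threshold`, `sensitivity`, `specificity`, plus `auc` and `score_name`.
#' @export
roc_curve <- function(scores, labels, score_name = deparse(substitute(scores))) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr),
                    sensitivity = c(0, sens),
                    specificity = c(1, spec))
  structure(list(points = pts, auc = auc(scores, labels),
                 score_name = score_name),
            class = "roc_curve")
}

# Bootstrap AUCs of several paired markers on shared resample indices.
# score_list: named list of numeric vectors (same patients). Returns an
# n_boot x length(score_list) matrix. Resamples with only one class are
# redrawn so the percentile grid stays fixed.
boot_aucs <- function(score_list, labels, n_boot, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.logical(labels)
  n <- length(labels)
  m <- length(score_list)
  out <- matrix(NA_real_, n_boot, m, dimnames = list(NULL, names(score_list)))
  for (i in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(labels[idx]) && any(!labels[idx])) break
    }
    li <- labels[idx]
    n1 <- sum(li)
    n0 <- n - n1
    for (j in seq_len(m)) {
      r <- rank(score_list[[j]][idx])
      out[i, j] <- (sum(r[li]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  out
}

#' Paired bootstrap comparison of two markers' AUCs
#'
#' Patients are resampled with replacement; both AUCs are recomputed on
#' identical indices, giving the resampling distribution of the AUC
#' difference. The 95% confidence interval is the 2.5/97.5 percentile of the
#' differences; the two-sided p-value inverts the resample distribution,
#' `p = 2 min(freq(delta* <= 0), freq(delta* >= 0))`, floored at
#' `2 / (n_boot + 1)` and capped at 1. Resamples containing a single class
#' are redrawn.
#'
#' @param scores_a,scores_b Paired marker vectors (same patients).
#' @param labels Logical vector, `TRUE` = positive.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `auc_comparison`: list with `auc_a`, `auc_b`,
#'   `delta`, `ci95` (of the difference), `auc_a_ci`, `auc_b_ci`,
#'   `p_two_sided`, `n_boot`, `seed`.
#' @export
bootstrap_compare <- function(scores_a, scores_b, labels, n_boot = 10000,
                              seed = NULL) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must be paired (equal length)")
  }
  if (n_boot < 100) warning("n_boot < 100 gives unstable percentile intervals")
  a <- auc(scores_a, labels)
  b <- auc(scores_b, labels)
  bs <- boot_aucs(list(a = scores_a, b = scores_b), labels, n_boot, seed)
  d <- bs[, 1] - bs[, 2]
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  p <- min(1, max(p, 2 / (n_boot + 1)))
  structure(
    list(auc_a = a, auc_b = b, delta = a - b,
         ci95 = unname(stats::quantile(d, c(0.025, 0.975))),
         auc_a_ci = unname(stats::quantile(bs[, 1], c(0.025, 0.975))),
         auc_b_ci = unname(stats::quantile(bs[, 2], c(0.025, 0.975))),
         p_two_sided = p, n_boot = n_boot, seed = seed),
    class = "auc_comparison"
  )
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.3f vs %.3f, delta %.3f (95%% CI %.3f, %.3f), p = %.4g [%d resamples]\n",
              x$auc_a, x$auc_b, x$delta, x$ci95[1], x$ci95[2],
              x$p_two_sided, x$n_boot))
  invisible(x)
}

#' Within-stratum logistic posteriors and stratified combination
#'
#' Within each stratum of an ordinal score, a univariate logistic model of
#' the outcome on the continuous marker yields posterior probabilities of
#' disease; concatenating the strata in order gives a combined score whose
#' ROC curve strings the within-stratum segments together. The combined
#' score is lexicographic — `stratum_index + posterior * (1 - epsilon)` — so
#' a patient in a higher stratum always outranks one in a lower stratum and
#' within-stratum ordering follows the posterior. When a stratum is too
#' small for a stable fit (fewer than `min_per_class` of either class),
#' constant, or separates perfectly, the posterior falls back to the
#' within-stratum midrank of the marker scaled to (0, 1), which preserves
#' the within-stratum ROC (the only property the analysis consumes).
#'
#' @param marker Continuous marker vector.
#' @param labels Logical vector, `TRUE` = positive.
#' @param strata Factor (or coercible) of ordinal strata, low to high.
#' @param min_per_class Minimum count of each class for a logistic fit
#'   (default 3).
#' @param epsilon Lexicographic gap guard (default 1e-6).
#' @return Object of class `stratified_combination`: list with `strata`
#'   (factor), `posterior`, `combined_score`, `fits` (per-stratum data
#'   frame: stratum, n, n_pos, method, intercept, slope).
#' @export
stratified_posteriors <- function(marker, labels, strata, min_per_class = 3,
                                  epsilon = 1e-6) {
  labels <- as.logical(labels)
  strata <- as.factor(strata)
  if (length(marker) != length(labels) || length(marker) != length(strata)) {
    stop("marker, labels and strata must have equal length")
  }
  posterior <- rep(NA_real_, length(marker))
  fits <- data.frame(stratum = levels(strata), n = NA_integer_,
                     n_pos = NA_integer_, method = NA_character_,
                     intercept = NA_real_, slope = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_along(levels(strata))) {
    in_k <- strata == levels(strata)[k]
    nk <- sum(in_k)
    fits$n[k] <- nk
    fits$n_pos[k] <- sum(labels[in_k])
    if (nk == 0L) {
      fits$method[k] <- "empty"
      message(sprintf("stratum '%s' is empty; skipped", levels(strata)[k]))
      next
    }
    mk <- marker[in_k]
    yk <- labels[in_k]
    use_rank <- sum(yk) < min_per_class || sum(!yk) < min_per_class ||
      length(unique(mk)) == 1L
    if (!use_rank) {
      fit <- withCallingHandlers(
        stats::glm(yk ~ mk, family = stats::binomial()),
        warning = function(w) {
          use_rank <<- TRUE
          invokeRestart("muffleWarning")
        }
      )
    }
    if (use_rank) {
      posterior[in_k] <- (rank(mk) - 0.5) / nk
      fits$method[k] <- "rank"
    } else {
      posterior[in_k] <- stats::fitted(fit)
      fits$method[k] <- "logistic"
      fits$intercept[k] <- stats::coef(fit)[1]
      fits$slope[k] <- stats::coef(fit)[2]
    }
  }
  combined <- as.integer(strata) + posterior * (1 - epsilon)
  structure(
    list(strata = strata, posterior = posterior, combined_score = combined,
         fits = fits),
    class = "stratified_combination"
  )
}

#' ROC curve of the stratified combination
#'
#' ROC/AUC of the lexicographic combined score; equivalent to concatenating
#' the within-stratum ROC segments in stratum order.
#'
#' @param combination A [stratified_posteriors()] result.
#' @param labels Logical vector, `TRUE` = positive.
#' @return A [roc_curve()].
#' @export
combined_roc <- function(combination, labels) {
  stopifnot(inherits(combination, "stratified_combination"))
  roc_curve(combination$combined_score, labels, score_name = "combined")
}

#' Per-category detection-rate table
#'
#' For each ordinal category, the number of negative and positive patients
#' and the detection rate (positives over all patients in the category) as a
#' percentage rounded to one decimal. Empty categories are reported with an
#' `NA` rate.
#'
#' @param pirads Integer vector of categories (1..5), or a data frame with
#'   columns `pirads` and `cspca`.
#' @param cspca Logical vector (ignored when `pirads` is a data frame).
#' @param categories Category levels to report (default 1..5).
#' @return Data frame: `pirads`, `n_negative`, `n_positive`, `rate_percent`.
#' @export
detection_rate_table <- function(pirads, cspca = NULL, categories = 1:5) {
  if (is.data.frame(pirads)) {
    cspca <- pirads$cspca
    pirads <- pirads$pirads
  }
  cspca <- as.logical(cspca)
  n_neg <- vapply(categories, function(k) sum(pirads == k & !cspca), integer(1))
  n_pos <- vapply(categories, function(k) sum(pirads == k & cspca), integer(1))
  total <- n_neg + n_pos
  rate <- ifelse(total > 0, round(100 * n_pos / total, 1), NA_real_)
  data.frame(pirads = categories, n_negative = n_neg, n_positive = n_pos,
             rate_percent = rate)
}
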
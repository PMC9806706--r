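#' Pipeline run configuration
#'
#' Consolidates the end-to-end settings: the synthetic cohort, the 5-mm
#' search margin, the two ADC b-value subsets (vendor-style b = 0/1000 and
#' the alternate b = 0/500/1000 from the same acquisition), the analyzed
#' regions and the bootstrap size.
#'
#' @param cohort A [cohort_config()].
#' @param margin_mm Search margin in mm (default 5).
#' @param adc_b_subsets Named list of b-value subsets (default vendor +
#'   alternate).
#' @param regions Analysis rows to produce; subset of
#'   `c("whole", "peripheral_zone", "transition_zone")`.
#' @param n_boot Bootstrap resamples for confidence intervals and p-values.
#' @param seed Integer seed for the statistical stage (the cohort has its
#'   own seed in `cohort`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), margin_mm = 5,
                       adc_b_subsets = list(vendor = c(0, 1000),
                                            alternate = c(0, 500, 1000)),
                       regions = c("whole", "peripheral_zone",
                                   "transition_zone"),
                       n_boot = 10000, seed = 17L) {
  stopifnot(inherits(cohort, "cohort_config"))
  regions <- match.arg(regions, several.ok = TRUE)
  if (is.null(names(adc_b_subsets)) || any(names(adc_b_subsets) == "")) {
    stop("adc_b_subsets must be a named list")
  }
  structure(
    list(cohort = cohort, margin_mm = margin_mm,
         adc_b_subsets = adc_b_subsets, regions = regions,
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Compute the patient-level markers for one patient
#'
#' Runs the per-patient imaging chain: median-b0 normalization over the
#' prostate, four-compartment fit over the margin-expanded prostate,
#' restriction-score map, ADC maps for each configured b-subset, and
#' max/min reduction over each margin-expanded search region.
#'
#' @param patient A [simulate_patient()] result (or any list with `dwi` and
#'   `segmentation` fields).
#' @param config A [run_config()].
#' @return Named list of markers: `max_rsirs_<region>` and
#'   `min_adc_<subset>_<region>` for each region/subset.
#' @export
patient_markers <- function(patient, config = run_config()) {
  seg <- patient$segmentation
  dwi <- normalize_by_median_b0(patient$dwi, seg$prostate)
  fit_mask <- expand_mask(seg$prostate, config$margin_mm, seg$voxel_size_mm)
  cmaps <- fit_compartments(dwi, fit_mask)
  rs <- compute_rsirs(cmaps)
  adcs <- lapply(config$adc_b_subsets, function(bs) fit_adc(dwi, fit_mask, bs))

  out <- list()
  for (region in config$regions) {
    search <- if (region == "transition_zone") "central_gland" else region
    red <- reduce_patient(rs, adcs[[1]], seg, search, config$margin_mm)
    out[[paste0("max_rsirs_", region)]] <- red$max_rsirs
    for (nm in names(adcs)) {
      redn <- reduce_patient(rs, adcs[[nm]], seg, search, config$margin_mm)
      out[[paste0("min_adc_", nm, "_", region)]] <- redn$min_adc
    }
  }
  out
}

# Merge PI-RADS 1-2 into a single lowest stratum (too few patients below 3
# for a stable within-stratum fit).
pirads_strata <- function(pirads) {
  factor(pmax(pirads, 2L), levels = 2:5,
         labels = c("<=2", "3", "4", "5"))
}

# One analysis row: AUCs + CIs for ADC variants, RSI_rs, PI-RADS and the
# stratified combination, plus the pairwise bootstrap comparisons. Cells
# that cannot be estimated (single class) are NA with a flag.
analyze_subgroup <- function(markers, labels, pirads, n_boot, seed) {
  if (!any(labels) || !any(!labels)) {
    return(list(estimable = FALSE, n = length(labels), n_pos = sum(labels)))
  }
  strat <- stratified_posteriors(markers$rsirs, labels, pirads_strata(pirads))
  scores <- c(markers, list(pirads = as.numeric(pirads),
                            combined = strat$combined_score))
  bs <- boot_aucs(scores, labels, n_boot, seed)
  aucs <- vapply(scores, auc, numeric(1), labels = labels)
  cis <- apply(bs, 2, stats::quantile, probs = c(0.025, 0.975))
  pair_p <- function(a, b) {
    d <- bs[, a] - bs[, b]
    min(1, max(2 * min(mean(d <= 0), mean(d >= 0)), 2 / (n_boot + 1)))
  }
  comparisons <- list(
    rsirs_vs_adc = pair_p("rsirs", "adc_vendor"),
    rsirs_vs_pirads = pair_p("rsirs", "pirads"),
    combined_vs_pirads = pair_p("combined", "pirads"),
    combined_vs_rsirs = pair_p("combined", "rsirs"),
    adc_alternate_vs_vendor = if ("adc_alternate" %in% colnames(bs)) {
      pair_p("adc_alternate", "adc_vendor")
    } else NA_real_
  )
  list(estimable = TRUE, n = length(labels), n_pos = sum(labels),
       auc = aucs, ci95 = cis, comparisons = comparisons,
       stratified = strat$fits)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured cohort, computes per-patient markers
#' (streaming one patient at a time to keep memory flat), and produces the
#' patient-level detection statistics: AUC with bootstrap confidence
#' intervals for minimum ADC (both b-subsets), maximum restriction score,
#' PI-RADS, and the stratified PI-RADS + restriction-score combination — for
#' the whole prostate and for the zone subgroups — plus within-PI-RADS
#' strata AUCs, pairwise bootstrap p-values, and the per-category
#' detection-rate table. ADC enters every ROC negated (lower ADC = more
#' suspicious).
#'
#' @param config A [run_config()].
#' @param progress Print a note every 25 patients.
#' @return Object of class `rsiscope_results`: list with `markers` (per-
#'   patient data frame), `analyses` (per-region results), `strata`
#'   (within-PI-RADS results), `detection_rates`, and `provenance`.
#' @export
run_all <- function(config = run_config(), progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_cohort(config$cohort, return_patients = FALSE)
  truth <- cohort$truth
  n <- nrow(truth)
  if (n == 0L) stop("cohort is empty; nothing to analyze")

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- simulate_patient(config$cohort, truth$grade_group[i],
                            truth$lesion_zone[i], truth$inflamed[i],
                            truth$pirads[i], truth$seed[i])
    rows[[i]] <- patient_markers(pat, config)
    if (progress && i %% 25 == 0) message(sprintf("  fitted %d/%d patients", i, n))
  }
  markers <- cbind(truth, as.data.frame(do.call(rbind, lapply(rows, unlist))))
  markers$cspca <- label_cspca(markers$grade_group)

  subset_names <- names(config$adc_b_subsets)
  region_scores <- function(region, idx) {
    sc <- list(rsirs = markers[[paste0("max_rsirs_", region)]][idx])
    for (nm in subset_names) {
      sc[[paste0("adc_", nm)]] <- -markers[[paste0("min_adc_", nm, "_", region)]][idx]
    }
    sc
  }

  analyses <- list()
  for (region in config$regions) {
    idx <- if (region == "whole") rep(TRUE, n) else markers$lesion_zone == region
    analyses[[region]] <- analyze_subgroup(
      region_scores(region, idx), markers$cspca[idx], markers$pirads[idx],
      config$n_boot, config$seed
    )
  }

  strata_results <- list()
  for (k in 3:5) {
    idx <- markers$pirads == k
    res <- if (sum(idx) > 0 && any(markers$cspca[idx]) && any(!markers$cspca[idx])) {
      sc <- region_scores("whole", idx)
      bs <- boot_aucs(sc, markers$cspca[idx], config$n_boot, config$seed + k)
      list(estimable = TRUE, n = sum(idx), n_pos = sum(markers$cspca[idx]),
           auc = vapply(sc, auc, numeric(1), labels = markers$cspca[idx]),
           ci95 = apply(bs, 2, stats::quantile, probs = c(0.025, 0.975)),
           p_rsirs_vs_adc = {
             d <- bs[, "rsirs"] - bs[, "adc_vendor"]
             min(1, max(2 * min(mean(d <= 0), mean(d >= 0)),
                        2 / (config$n_boot + 1)))
           })
    } else {
      list(estimable = FALSE, n = sum(idx), n_pos = sum(markers$cspca[idx]))
    }
    strata_results[[paste0("pirads_", k)]] <- res
  }

  structure(
    list(markers = markers,
         analyses = analyses,
         strata = strata_results,
         detection_rates = detection_rate_table(markers$pirads, markers$cspca),
         provenance = list(
           n_patients = n, cohort_seed = config$cohort$seed,
           stats_seed = config$seed, n_boot = config$n_boot,
           margin_mm = config$margin_mm,
           package_version = as.character(utils::packageVersion("rsiscope")),
           r_version = R.version.string,
           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "rsiscope_results"
  )
}

#' Summary table of a pipeline run
#'
#' One row per analysis (whole prostate, zone subgroups, within-PI-RADS
#' strata) with AUC and 95% CI per marker, mirroring the structure of a
#' clinical comparison table. Not-estimable cells are NA.
#'
#' @param results A [run_all()] result.
#' @return Data frame.
#' @export
results_table <- function(results) {
  stopifnot(inherits(results, "rsiscope_results"))
  fmt_row <- function(name, res) {
    grab <- function(marker) {
      if (!isTRUE(res$estimable) || !marker %in% names(res$auc)) {
        return(c(NA_real_, NA_real_, NA_real_))
      }
      c(res$auc[[marker]], res$ci95[1, marker], res$ci95[2, marker])
    }
    v <- c(grab("adc_vendor"), grab("adc_alternate"), grab("rsirs"),
           grab("pirads"), grab("combined"))
    names(v) <- as.vector(outer(c("auc", "lo", "hi"),
                                c("adc_vendor", "adc_alternate", "rsirs",
                                  "pirads", "combined"),
                                function(a, b) paste(b, a, sep = "_")))
    data.frame(analysis = name, n = res$n, n_pos = res$n_pos, t(v))
  }
  rows <- c(lapply(names(results$analyses),
                   function(r) fmt_row(r, results$analyses[[r]])),
            lapply(names(results$strata),
                   function(r) fmt_row(r, results$strata[[r]])))
  do.call(rbind, rows)
}

#' Write a results bundle to disk
#'
#' Emits `results.json` (full statistics), `summary_table.csv`,
#' `detection_rates.csv` and `cohort_markers.csv` under `dir`.
#'
#' @param results A [run_all()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "rsiscope_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(analyses = results$analyses, strata = results$strata,
         detection_rates = results$detection_rates,
         provenance = results$provenance),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, null = "null"
  )
  utils::write.csv(results_table(results),
                   file.path(dir, "summary_table.csv"), row.names = FALSE)
  utils::write.csv(results$detection_rates,
                   file.path(dir, "detection_rates.csv"), row.names = FALSE)
  utils::write.csv(results$markers, file.path(dir, "cohort_markers.csv"),
                   row.names = FALSE)
  invisible(dir)
}
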
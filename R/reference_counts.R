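#' Published per-category biopsy outcome counts
#'
#' Cross-tabulation of highest PI-RADS category against biopsy outcome
#' (benign or grade group 1 vs clinically significant cancer, grade group
#' >= 2) from the published 151-patient clinical cohort. These counts
#' calibrate the default PI-RADS detection model of the synthetic cohort
#' and serve as a worked example for [detection_rate_table()].
#'
#' @return Data frame with columns `pirads`, `n_negative`, `n_positive`.
#' @export
pirads_reference_counts <- function() {
  data.frame(
    pirads = 1:5,
    n_negative = c(0L, 2L, 23L, 30L, 10L),
    n_positive = c(0L, 3L, 4L, 25L, 54L)
  )
}

#' Published grade-group marginal counts
#'
#' Number of patients per highest histopathology grade group in the published
#' cohort (0 = benign, 1..5 = Gleason-derived grade groups). Used as the
#' default grade-group sampling distribution of the synthetic cohort.
#'
#' @return Named integer vector of length 6 (gg0..gg5), summing to 151.
#' @export
grade_group_reference_counts <- function() {
  c(gg0 = 25L, gg1 = 40L, gg2 = 38L, gg3 = 20L, gg4 = 16L, gg5 = 12L)
}

#' Published zone-subgroup composition
#'
#' Patients whose lesions were confined to one prostate zone, broken down by
#' biopsy outcome: peripheral-zone-only and transition-zone-only subgroups.
#' The synthetic cohort uses these to set zone probabilities conditional on
#' disease status.
#'
#' @return Data frame with columns `zone`, `n_benign`, `n_gg1`, `n_cspca`.
#' @export
zone_reference_counts <- function() {
  data.frame(
    zone = c("peripheral_zone", "transition_zone"),
    n_benign = c(15L, 14L),
    n_gg1 = c(23L, 15L),
    n_cspca = c(65L, 8L)
  )
}
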
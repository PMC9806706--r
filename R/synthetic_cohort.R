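#' PI-RADS detection model
#'
#' Conditional distribution of the highest PI-RADS category given disease
#' status (clinically significant cancer vs benign / grade group 1). The
#' default is calibrated from the published per-category biopsy outcome
#' counts ([pirads_reference_counts()]), so that the long-run per-category
#' detection rates of a simulated cohort match the published table (e.g.
#' 84.4% of PI-RADS 5 patients harboring significant cancer).
#'
#' @param counts Data frame like [pirads_reference_counts()].
#' @return Object of class `pirads_detection_model`: list with `positive`
#'   and `negative` probability vectors over categories 1..5.
#' @export
pirads_detection_model <- function(counts = pirads_reference_counts()) {
  stopifnot(all(c("pirads", "n_negative", "n_positive") %in% names(counts)))
  pos <- counts$n_positive / sum(counts$n_positive)
  neg <- counts$n_negative / sum(counts$n_negative)
  names(pos) <- names(neg) <- counts$pirads
  validate_probs(pos, "positive")
  validate_probs(neg, "negative")
  structure(list(positive = pos, negative = neg),
            class = "pirads_detection_model")
}

validate_probs <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("%s probabilities must be nonnegative and sum to 1", what))
  }
  invisible(p)
}

#' Sample PI-RADS categories given disease status
#'
#' Draws ordinal categories 1..5 from the detection model conditional on each
#' patient's clinically-significant-cancer status. Uses the current RNG state.
#'
#' @param is_cspca Logical vector.
#' @param model A [pirads_detection_model()].
#' @return Integer vector of categories, same length as `is_cspca`.
#' @export
sample_pirads <- function(is_cspca, model = pirads_detection_model()) {
  stopifnot(inherits(model, "pirads_detection_model"))
  validate_probs(model$positive, "positive")
  validate_probs(model$negative, "negative")
  out <- integer(length(is_cspca))
  npos <- sum(is_cspca)
  if (npos > 0) out[is_cspca] <- sample.int(5L, npos, TRUE, model$positive)
  if (npos < length(is_cspca)) {
    out[!is_cspca] <- sample.int(5L, length(is_cspca) - npos, TRUE, model$negative)
  }
  out
}

#' Synthetic cohort configuration
#'
#' All tunable parameters of the synthetic DWI cohort. Defaults reproduce the
#' structure of the published 151-patient clinical cohort: grade-group
#' marginals and PI-RADS detection rates from the published tables, zone
#' probabilities from the zone-subgroup composition, the four-b-value
#' acquisition protocol, 2.5 x 2.5 x 6 mm voxels, and Rician noise giving a
#' b = 0 signal-to-noise ratio of about 20.
#'
#' @param n_patients Number of patients.
#' @param grade_group_probs Probability 6-vector over grade groups 0 (benign)
#'   to 5; must sum to 1.
#' @param pirads_given_cspca A [pirads_detection_model()].
#' @param lesion_zone_probs Named 2-vector: probability of a peripheral-zone
#'   (vs transition-zone) lesion for `positive` and `negative` patients.
#' @param noise_sigma Rician noise scale per channel, in median-b0-normalized
#'   units (0.05 = SNR 20 at b = 0).
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @param grid_shape Integer 3-vector of voxel counts, each >= 8.
#' @param seed Integer RNG seed for the cohort.
#' @param protocol An [acquisition_protocol()].
#' @param archetypes Named list from [default_archetypes()].
#' @param tumor_c1_base,tumor_c1_per_grade Grade modulation of the tumor
#'   restricted fraction (see [tumor_archetype_for_grade()]).
#' @param lesion_radius_mm Ellipsoidal lesion semi-axes, mm.
#' @param inflammation_prob Probability that a benign / grade group 1 patient
#'   carries a focal inflammation region (the low-ADC confounder).
#' @param prostate_semi_axes_mm Prostate ellipsoid semi-axes, mm (default
#'   gives a gland of about 40 ml).
#' @param central_gland_scale Relative size of the central gland ellipsoid.
#' @param central_gland_shift_mm Anterior shift of the central gland, mm.
#' @param signal_scale Arbitrary scanner-unit multiplier applied to the raw
#'   simulated signal (removed again by median-b0 normalization).
#' @param min_lesion_voxels Minimum acceptable lesion size in voxels.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 151,
                          grade_group_probs = grade_group_reference_counts() /
                            sum(grade_group_reference_counts()),
                          pirads_given_cspca = pirads_detection_model(),
                          lesion_zone_probs = c(positive = 65 / 73,
                                                negative = 38 / 67),
                          noise_sigma = 0.05,
                          voxel_size_mm = c(2.5, 2.5, 6),
                          grid_shape = c(40L, 40L, 14L),
                          seed = 20210521L,
                          protocol = acquisition_protocol(),
                          archetypes = default_archetypes(),
                          tumor_c1_base = 0.14,
                          tumor_c1_per_grade = 0.07,
                          lesion_radius_mm = c(7, 7, 5.5),
                          inflammation_prob = 0.5,
                          prostate_semi_axes_mm = c(24, 21, 19),
                          central_gland_scale = 0.62,
                          central_gland_shift_mm = c(0, -5, 0),
                          signal_scale = 400,
                          min_lesion_voxels = 5L) {
  grade_group_probs <- as.numeric(grade_group_probs)
  if (length(grade_group_probs) != 6L) stop("grade_group_probs must have length 6")
  validate_probs(grade_group_probs, "grade group")
  stopifnot(inherits(pirads_given_cspca, "pirads_detection_model"))
  if (!all(c("positive", "negative") %in% names(lesion_zone_probs)) ||
      any(lesion_zone_probs < 0) || any(lesion_zone_probs > 1)) {
    stop("lesion_zone_probs needs 'positive' and 'negative' entries in [0, 1]")
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) stop("noise_sigma must be >= 0")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    stop("grid_shape must be a 3-vector with all components >= 8")
  }
  if (n_patients < 0) stop("n_patients must be nonnegative")
  structure(
    list(n_patients = as.integer(n_patients),
         grade_group_probs = grade_group_probs,
         pirads_given_cspca = pirads_given_cspca,
         lesion_zone_probs = lesion_zone_probs,
         noise_sigma = noise_sigma,
         voxel_size_mm = as.numeric(voxel_size_mm),
         grid_shape = grid_shape,
         seed = as.integer(seed),
         protocol = protocol,
         archetypes = archetypes,
         tumor_c1_base = tumor_c1_base,
         tumor_c1_per_grade = tumor_c1_per_grade,
         lesion_radius_mm = as.numeric(lesion_radius_mm),
         inflammation_prob = inflammation_prob,
         prostate_semi_axes_mm = as.numeric(prostate_semi_axes_mm),
         central_gland_scale = central_gland_scale,
         central_gland_shift_mm = as.numeric(central_gland_shift_mm),
         signal_scale = signal_scale,
         min_lesion_voxels = as.integer(min_lesion_voxels)),
    class = "cohort_config"
  )
}

# Voxel-center coordinates in mm, grid centered at the origin.
voxel_coordinates_mm <- function(grid_shape, voxel_size_mm) {
  lapply(1:3, function(d) {
    (seq_len(grid_shape[d]) - (grid_shape[d] + 1) / 2) * voxel_size_mm[d]
  })
}

# Logical mask of an axis-aligned ellipsoid given center and semi-axes in mm.
ellipsoid_mask <- function(grid_shape, voxel_size_mm, center_mm, semi_axes_mm) {
  co <- voxel_coordinates_mm(grid_shape, voxel_size_mm)
  dx2 <- ((co[[1]] - center_mm[1]) / semi_axes_mm[1])^2
  dy2 <- ((co[[2]] - center_mm[2]) / semi_axes_mm[2])^2
  dz2 <- ((co[[3]] - center_mm[3]) / semi_axes_mm[3])^2
  q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(q <= 1, dim = grid_shape)
}

#' Build the synthetic prostate segmentation
#'
#' The gland is an axis-aligned ellipsoid at the grid center; the central
#' gland (transition + central zones) is a smaller, anteriorly shifted
#' ellipsoid inside it and the peripheral zone is the remaining posterior
#' rim, so the two zones partition the prostate.
#'
#' @param config A [cohort_config()].
#' @return A [segmentation_set()].
#' @export
build_segmentation <- function(config) {
  prostate <- ellipsoid_mask(config$grid_shape, config$voxel_size_mm,
                             c(0, 0, 0), config$prostate_semi_axes_mm)
  cg <- ellipsoid_mask(config$grid_shape, config$voxel_size_mm,
                       config$central_gland_shift_mm,
                       config$prostate_semi_axes_mm * config$central_gland_scale)
  cg <- cg & prostate
  segmentation_set(prostate, prostate & !cg, cg, config$voxel_size_mm)
}

# Sample an ellipsoidal lesion inside zone_mask; returns a logical array.
# Retries a handful of centers and keeps the largest intersection.
place_lesion <- function(zone_mask, config) {
  idx <- which(zone_mask)
  if (length(idx) == 0L) stop("zone mask is empty; grid too small to place lesion")
  co <- voxel_coordinates_mm(config$grid_shape, config$voxel_size_mm)
  best <- NULL
  for (try in seq_len(25L)) {
    center_idx <- arrayInd(sample(idx, 1L), config$grid_shape)
    center_mm <- c(co[[1]][center_idx[1]], co[[2]][center_idx[2]],
                   co[[3]][center_idx[3]])
    lesion <- ellipsoid_mask(config$grid_shape, config$voxel_size_mm,
                             center_mm, config$lesion_radius_mm) & zone_mask
    if (is.null(best) || sum(lesion) > sum(best)) best <- lesion
    if (sum(best) >= config$min_lesion_voxels) break
  }
  if (sum(best) < config$min_lesion_voxels) {
    stop(sprintf("grid too small to place a lesion of >= %d voxels",
                 config$min_lesion_voxels))
  }
  best
}

#' Simulate one synthetic patient
#'
#' Paints tissue archetypes onto the segmentation (peripheral zone =
#' benign epithelium, central gland = stroma, outside = periprostatic
#' tissue), places a grade-modulated tumor lesion when grade group >= 1 and
#' optionally a focal inflammation region in benign / grade group 1
#' patients, draws per-voxel compartment fractions, and synthesizes the
#' Rician-noised multi-b DWI stack in arbitrary scanner units.
#'
#' @param config A [cohort_config()].
#' @param grade_group Integer 0..5.
#' @param zone `"peripheral_zone"` or `"transition_zone"` (lesion location;
#'   also used for the inflammation region).
#' @param inflamed Logical; add the inflammation confounder region.
#' @param pirads Optional ordinal category to attach.
#' @param seed Optional integer seed for this patient.
#' @return Object of class `synthetic_patient`: list with `dwi`
#'   ([dwi_series()]), `segmentation` ([segmentation_set()]), `truth` (grade
#'   group, lesion zone, lesion mask, inflammation flag) and `pirads`.
#' @export
simulate_patient <- function(config, grade_group, zone = "peripheral_zone",
                             inflamed = FALSE, pirads = NA_integer_,
                             seed = NULL) {
  if (!grade_group %in% 0:5) stop("grade_group must be in 0..5")
  if (!zone %in% c("peripheral_zone", "transition_zone")) {
    stop("zone must be 'peripheral_zone' or 'transition_zone'")
  }
  if (!is.null(seed)) set.seed(seed)
  seg <- build_segmentation(config)
  zone_mask <- if (zone == "peripheral_zone") seg$peripheral_zone else seg$central_gland

  n_vox <- prod(config$grid_shape)
  arch <- config$archetypes
  tissue <- array(1L, dim = config$grid_shape)           # periprostatic
  tissue[seg$peripheral_zone] <- 2L                      # benign epithelium
  tissue[seg$central_gland] <- 3L                        # stroma
  tumor <- if (grade_group >= 1L) {
    tumor_archetype_for_grade(grade_group, config$tumor_c1_base,
                              config$tumor_c1_per_grade,
                              arch$tumor$fraction_dispersion)
  } else {
    arch$tumor                                   # placeholder; no voxel uses it
  }
  base_list <- list(arch$periprostatic, arch$benign_epithelium, arch$stroma,
                    tumor, arch$inflammation)

  lesion <- array(FALSE, dim = config$grid_shape)
  if (grade_group >= 1L) {
    lesion <- place_lesion(zone_mask, config)
    tissue[lesion] <- 4L
  }
  if (isTRUE(inflamed) && grade_group <= 1L) {
    avoid <- if (grade_group >= 1L) zone_mask & !lesion else zone_mask
    inflammation <- place_lesion(avoid, config)
    tissue[inflammation & !lesion] <- 5L
  }

  base_mat <- t(vapply(base_list, function(a) a$fractions, numeric(4)))
  disp <- vapply(base_list, function(a) a$fraction_dispersion, numeric(1))
  tv <- as.integer(tissue)
  frac <- base_mat[tv, , drop = FALSE] +
    matrix(stats::rnorm(n_vox * 4L), n_vox, 4L) * disp[tv]
  frac[frac < 0] <- 0

  sig <- simulate_signal_matrix(frac, config$protocol$b_values,
                                config$noise_sigma) * config$signal_scale
  dwi <- dwi_series(array(sig, c(config$grid_shape, length(config$protocol$b_values))),
                    config$protocol$b_values, config$voxel_size_mm)
  structure(
    list(dwi = dwi, segmentation = seg,
         truth = list(grade_group = as.integer(grade_group), lesion_zone = zone,
                      lesion_mask = lesion, inflamed = isTRUE(inflamed)),
         pirads = as.integer(pirads)),
    class = "synthetic_patient"
  )
}

#' Simulate a seeded synthetic cohort
#'
#' Draws patient-level truth (grade group, lesion zone, PI-RADS category,
#' inflammation flag) from the configured distributions, then simulates each
#' patient's imaging from an independently derived per-patient seed, so that
#' the cohort is fully reproducible and individual patients can be
#' re-simulated in isolation from the truth table alone.
#'
#' @param config A [cohort_config()].
#' @param return_patients If `FALSE`, only the truth table is returned and
#'   imaging is left to be generated on demand via [simulate_patient()]
#'   (useful to keep memory flat when streaming a large cohort).
#' @return List with `truth` (data frame: patient_id, grade_group, pirads,
#'   lesion_zone, cspca, inflamed, seed) and `patients` (list of
#'   [simulate_patient()] results, or `NULL`).
#' @export
simulate_cohort <- function(config = cohort_config(), return_patients = TRUE) {
  set.seed(config$seed)
  n <- config$n_patients
  if (n == 0L) {
    truth <- data.frame(patient_id = character(0), grade_group = integer(0),
                        pirads = integer(0), lesion_zone = character(0),
                        cspca = logical(0), inflamed = logical(0),
                        seed = integer(0))
    return(list(truth = truth, patients = list()))
  }
  gg <- sample(0:5, n, replace = TRUE, prob = config$grade_group_probs)
  cspca <- gg >= 2L
  p_pz <- ifelse(cspca, config$lesion_zone_probs[["positive"]],
                 config$lesion_zone_probs[["negative"]])
  zone <- ifelse(stats::runif(n) < p_pz, "peripheral_zone", "transition_zone")
  pirads <- sample_pirads(cspca, config$pirads_given_cspca)
  inflamed <- gg <= 1L & stats::runif(n) < config$inflammation_prob
  pat_seed <- sample.int(.Machine$integer.max - 1L, n)
  truth <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    grade_group = as.integer(gg),
    pirads = as.integer(pirads),
    lesion_zone = zone,
    cspca = cspca,
    inflamed = inflamed,
    seed = pat_seed,
    stringsAsFactors = FALSE
  )
  patients <- NULL
  if (return_patients) {
    patients <- lapply(seq_len(n), function(i) {
      simulate_patient(config, truth$grade_group[i], truth$lesion_zone[i],
                       truth$inflamed[i], truth$pirads[i], truth$seed[i])
    })
    names(patients) <- truth$patient_id
  }
  list(truth = truth, patients = patients)
}
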
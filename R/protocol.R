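#' Fixed compartmental diffusion coefficients
#'
#' The four-compartment model uses empirically determined apparent diffusion
#' coefficients for the restricted, hindered and free water compartments.
#' The fourth (vascular flow) compartment decays so fast that it contributes
#' only at b = 0; it is handled as an indicator column in the design matrix
#' rather than by a finite coefficient (see [decay_design_matrix()]).
#'
#' @return Named numeric vector of length 3, units mm^2/s.
#' @export
rsi_diffusion_coeffs <- function() {
  c(restricted = 1.0e-4, hindered = 1.8e-3, free = 3.6e-3)
}

#' Diffusion acquisition protocol
#'
#' Describes the multi-b-value acquisition: one direction-averaged volume per
#' b-value. Echo/repetition times are metadata only and play no role in the
#' signal model.
#'
#' @param b_values Numeric vector of diffusion weightings in s/mm^2, strictly
#'   increasing, starting at 0.
#' @param directions_per_b Integer vector, number of diffusion directions
#'   averaged into each b-value volume (same length as `b_values`, each >= 1).
#' @param echo_time Echo time in ms (metadata).
#' @param repetition_time Repetition time in ms (metadata).
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(b_values = c(0, 500, 1000, 2000),
                                 directions_per_b = c(2, 6, 6, 12),
                                 echo_time = 68,
                                 repetition_time = 4500) {
  b_values <- as.numeric(b_values)
  if (length(b_values) < 2L || b_values[1] != 0 || any(diff(b_values) <= 0)) {
    stop("b_values must be strictly increasing and start at 0")
  }
  directions_per_b <- as.integer(directions_per_b)
  if (length(directions_per_b) != length(b_values) || any(directions_per_b < 1L)) {
    stop("directions_per_b must match b_values in length, each >= 1")
  }
  structure(
    list(b_values = b_values, directions_per_b = directions_per_b,
         echo_time = echo_time, repetition_time = repetition_time),
    class = "acquisition_protocol"
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("Diffusion acquisition protocol\n")
  cat("  b-values (s/mm^2):", paste(x$b_values, collapse = ", "), "\n")
  cat("  directions per b: ", paste(x$directions_per_b, collapse = ", "), "\n")
  invisible(x)
}

#' Tissue archetype for the synthetic cohort
#'
#' An archetype is a canonical 4-vector of compartment signal contributions
#' (C1..C4, in median-b0-normalized units) plus a per-voxel dispersion used
#' when painting a tissue region: each voxel draws its fractions from a
#' normal around the archetype, truncated at zero.
#'
#' @param name Label, e.g. "tumor", "benign_epithelium", "stroma",
#'   "inflammation", "periprostatic".
#' @param fractions Nonnegative numeric 4-vector (restricted, hindered, free,
#'   flow); their sum should be near 1 (at most 1.5).
#' @param fraction_dispersion Nonnegative standard deviation of the per-voxel
#'   truncated-normal variation, in the same normalized units.
#' @return An object of class `tissue_archetype`.
#' @export
tissue_archetype <- function(name, fractions, fraction_dispersion = 0) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 4L || any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("fractions must be a nonnegative finite 4-vector")
  }
  if (sum(fractions) > 1.5) {
    stop("fractions sum exceeds 1.5; signal is in median-b0-normalized units")
  }
  if (!is.finite(fraction_dispersion) || fraction_dispersion < 0) {
    stop("fraction_dispersion must be nonnegative")
  }
  structure(
    list(name = as.character(name), fractions = fractions,
         fraction_dispersion = fraction_dispersion),
    class = "tissue_archetype"
  )
}

#' Default tissue archetypes
#'
#' Compartment-fraction defaults for the synthetic cohort. Tumor voxels carry
#' a high restricted (C1) contribution that rises with grade group (see
#' [tumor_archetype_for_grade()]); inflammation is an ADC confounder with a
#' slow mono-exponential decay but a restricted contribution well below
#' clinically significant tumor; periprostatic tissue (outside the gland)
#' has reduced overall signal amplitude. These are simulator parameters,
#' chosen to reproduce the qualitative tumor/benign dissociation the
#' analysis assumes, not measured tissue values.
#'
#' @return Named list of `tissue_archetype` objects.
#' @export
default_archetypes <- function() {
  list(
    tumor = tissue_archetype("tumor", c(0.42, 0.43, 0.10, 0.05), 0.06),
    benign_epithelium = tissue_archetype("benign_epithelium",
                                         c(0.06, 0.40, 0.50, 0.04), 0.04),
    stroma = tissue_archetype("stroma", c(0.10, 0.55, 0.30, 0.05), 0.04),
    inflammation = tissue_archetype("inflammation",
                                    c(0.22, 0.72, 0.03, 0.03), 0.05),
    periprostatic = tissue_archetype("periprostatic",
                                     c(0.02, 0.06, 0.08, 0.02), 0.03)
  )
}

#' Tumor archetype modulated by histologic grade group
#'
#' The restricted-compartment mean rises linearly with grade group while the
#' hindered compartment absorbs the complement, keeping the b = 0 amplitude
#' near 1. Grade group 1 tumors sit close to benign extremes, so patient-level
#' separation comes from grade group >= 2 disease.
#'
#' @param grade_group Integer in 1..5.
#' @param c1_base Restricted fraction intercept (default 0.14).
#' @param c1_per_grade Restricted fraction increment per grade group
#'   (default 0.07).
#' @param dispersion Per-voxel dispersion (default 0.06).
#' @return A `tissue_archetype`.
#' @export
tumor_archetype_for_grade <- function(grade_group, c1_base = 0.14,
                                      c1_per_grade = 0.07, dispersion = 0.06) {
  if (!grade_group %in% 1:5) stop("grade_group must be in 1..5")
  c1 <- c1_base + c1_per_grade * grade_group
  free <- 0.10
  flow <- 0.05
  hindered <- max(0, 1 - c1 - free - flow)
  tissue_archetype("tumor", c(c1, hindered, free, flow), dispersion)
}
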
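#' Expand a mask by a physical margin
#'
#' Morphological dilation in millimeter units: the output contains exactly
#' the voxels whose center lies within Euclidean distance `margin_mm` of some
#' input-voxel center, honoring anisotropic voxel sizes (e.g. with
#' 2.5 x 2.5 x 6 mm voxels a 5 mm margin grows in-plane but not
#' through-plane). Always a superset of the input; `margin_mm = 0` is the
#' identity.
#'
#' @param mask Logical 3-D array.
#' @param margin_mm Nonnegative margin in mm.
#' @param voxel_size_mm Numeric 3-vector of voxel edge lengths in mm.
#' @return Logical array of the same dimension.
#' @export
expand_mask <- function(mask, margin_mm, voxel_size_mm) {
  if (!is.finite(margin_mm) || margin_mm < 0) stop("margin_mm must be >= 0")
  dims <- dim(mask)
  r <- floor(margin_mm / voxel_size_mm)
  out <- array(FALSE, dims)
  for (dz in -r[3]:r[3]) {
    for (dy in -r[2]:r[2]) {
      for (dx in -r[1]:r[1]) {
        d2 <- (dx * voxel_size_mm[1])^2 + (dy * voxel_size_mm[2])^2 +
          (dz * voxel_size_mm[3])^2
        if (d2 > margin_mm^2) next
        lo <- pmax(1, 1 + c(dx, dy, dz))
        hi <- pmin(dims, dims + c(dx, dy, dz))
        if (any(lo > hi)) next
        xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
        out[xs, ys, zs] <- out[xs, ys, zs] |
          mask[xs - dx, ys - dy, zs - dz]
      }
    }
  }
  out
}

#' Clinically significant cancer label from grade group
#'
#' Patients whose biopsies show only benign tissue (grade group 0) or grade
#' group 1 cancer (Gleason <= 6) are negatives; grade group >= 2 is
#' clinically significant.
#'
#' @param grade_group Integer vector with values in 0..5.
#' @return Logical vector.
#' @export
label_cspca <- function(grade_group) {
  if (any(!grade_group %in% 0:5)) stop("grade_group values must be in 0..5")
  grade_group >= 2
}

#' Reduce voxel maps to patient-level markers
#'
#' The automated patient-level markers: the maximum restriction score and the
#' minimum ADC over the margin-expanded search region. `search_region`
#' selects which base mask is expanded — the whole prostate for the primary
#' analysis, or one zone for zone-restricted analyses. No-data voxels (`NA`,
#' e.g. outside the fitted mask or with non-positive signals) are excluded
#' from both reductions.
#'
#' @param rsirs A [compute_rsirs()] result (or any list with a `value` array).
#' @param adc A [fit_adc()] result.
#' @param seg A [segmentation_set()] co-registered with the maps.
#' @param search_region `"whole"`, `"peripheral_zone"` or `"central_gland"`.
#' @param margin_mm Margin applied to the region mask (default 5).
#' @return List with `max_rsirs`, `min_adc`, `search_region`, `margin_mm`,
#'   `n_voxels` (valid voxels used for each marker).
#' @export
reduce_patient <- function(rsirs, adc, seg,
                           search_region = c("whole", "peripheral_zone",
                                             "central_gland"),
                           margin_mm = 5) {
  search_region <- match.arg(search_region)
  base <- switch(search_region,
                 whole = seg$prostate,
                 peripheral_zone = seg$peripheral_zone,
                 central_gland = seg$central_gland)
  region <- expand_mask(base, margin_mm, seg$voxel_size_mm)
  rs_vals <- rsirs$value[region]
  rs_vals <- rs_vals[!is.na(rs_vals)]
  adc_vals <- adc$value[region]
  adc_vals <- adc_vals[!is.na(adc_vals)]
  if (length(rs_vals) == 0L) {
    stop("no valid restriction-score voxel in the search region")
  }
  if (length(adc_vals) == 0L) {
    stop("no valid ADC voxel in the search region")
  }
  list(max_rsirs = max(rs_vals), min_adc = min(adc_vals),
       search_region = search_region, margin_mm = margin_mm,
       n_voxels = c(rsirs = length(rs_vals), adc = length(adc_vals)))
}
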
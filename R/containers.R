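#' Per-patient diffusion-weighted series
#'
#' Holds one direction-averaged signal volume per b-value as a 4-D array
#' indexed (x, y, z, b-index), with voxel geometry. Signals are in arbitrary
#' scanner units until [normalize_by_median_b0()] sets the `normalized` flag.
#'
#' @param signal 4-D numeric array, 4th dimension indexing b-values.
#' @param b_values Numeric vector matching the 4th dimension.
#' @param voxel_size_mm Numeric 3-vector, voxel edge lengths in mm.
#' @param normalized Logical; whether median-b0 normalization was applied.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(signal, b_values, voxel_size_mm, normalized = FALSE) {
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L) stop("signal must be a 4-D array (x, y, z, b)")
  if (dim(signal)[4] != length(b_values)) {
    stop("4th dimension of signal must match length(b_values)")
  }
  if (any(!is.finite(signal))) stop("signal values must be finite")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be a positive 3-vector")
  }
  structure(
    list(signal = signal, b_values = as.numeric(b_values),
         voxel_size_mm = voxel_size_mm, normalized = isTRUE(normalized)),
    class = "dwi_series"
  )
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("DWI series: %d x %d x %d voxels, b = %s s/mm^2, %s\n",
              d[1], d[2], d[3], paste(x$b_values, collapse = "/"),
              if (x$normalized) "median-b0 normalized" else "raw units"))
  invisible(x)
}

#' Prostate segmentation set
#'
#' Boolean masks for the whole prostate, the peripheral zone and the central
#' gland (transition + central zones). The two zones must be disjoint and
#' partition the prostate.
#'
#' @param prostate,peripheral_zone,central_gland Logical 3-D arrays of equal
#'   dimension.
#' @param voxel_size_mm Numeric 3-vector in mm.
#' @return An object of class `segmentation_set`.
#' @export
segmentation_set <- function(prostate, peripheral_zone, central_gland,
                             voxel_size_mm) {
  dims <- dim(prostate)
  if (!identical(dims, dim(peripheral_zone)) || !identical(dims, dim(central_gland))) {
    stop("all masks must share the same dimensions")
  }
  if (any(peripheral_zone & central_gland)) {
    stop("peripheral zone and central gland must be disjoint")
  }
  if (!identical(which(peripheral_zone | central_gland), which(prostate))) {
    stop("peripheral zone and central gland must partition the prostate mask")
  }
  structure(
    list(prostate = prostate, peripheral_zone = peripheral_zone,
         central_gland = central_gland,
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "segmentation_set"
  )
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat(sprintf("Segmentation: prostate %d vox (PZ %d, central gland %d)\n",
              sum(x$prostate), sum(x$peripheral_zone), sum(x$central_gland)))
  invisible(x)
}
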
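#' Mono-exponential ADC map from a b-value subset
#'
#' Conventional apparent diffusion coefficient: per masked voxel, the
#' negative slope of the ordinary least-squares line of log signal against
#' b over the chosen b-values (for two b-values this reduces to the familiar
#' `ln(S0/S1) / (b1 - b0)`). The default subset b = 0/1000 mimics the
#' vendor-style clinical map; b = 0/500/1000 gives the alternate three-point
#' map from the same acquisition. Voxels with any non-positive signal in the
#' subset are flagged no-data (`NA`) rather than clipped, so noise-driven
#' zeros cannot masquerade as extreme diffusion values in the minimum-ADC
#' reduction.
#'
#' @param series A [dwi_series()] (raw or normalized; ADC is invariant to a
#'   global positive scaling).
#' @param mask Logical 3-D array of voxels to fit.
#' @param b_subset b-values to use; must include 0 and be present in the
#'   series (default `c(0, 1000)`).
#' @return Object of class `adc_map`: list with `value` (3-D array, mm^2/s,
#'   `NA` outside mask or at no-data voxels), `b_subset`, `voxel_size_mm`.
#' @export
fit_adc <- function(series, mask, b_subset = c(0, 1000)) {
  stopifnot(inherits(series, "dwi_series"))
  b_subset <- sort(as.numeric(b_subset))
  if (length(b_subset) < 2L || !0 %in% b_subset) {
    stop("b_subset must contain at least two b-values including 0")
  }
  pos <- match(b_subset, series$b_values)
  if (anyNA(pos)) {
    stop(sprintf("b-values %s not present in the series",
                 paste(b_subset[is.na(pos)], collapse = ", ")))
  }
  if (!any(mask)) stop("mask is empty")
  dims <- dim(series$signal)[1:3]
  idx <- which(mask)
  S <- matrix(series$signal, prod(dims), dim(series$signal)[4])[idx, pos, drop = FALSE]
  ok <- rowSums(S <= 0) == 0L
  adc_vals <- rep(NA_real_, length(idx))
  if (any(ok)) {
    logS <- log(S[ok, , drop = FALSE])
    bc <- b_subset - mean(b_subset)
    # OLS slope of log S on b, vectorized across voxels
    slope <- (logS %*% bc) / sum(bc^2)
    adc_vals[ok] <- -drop(slope)
  }
  out <- array(NA_real_, dims)
  out[idx] <- adc_vals
  structure(
    list(value = out, b_subset = b_subset, voxel_size_mm = series$voxel_size_mm),
    class = "adc_map"
  )
}
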
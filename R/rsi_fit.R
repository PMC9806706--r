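#' Normalize a DWI series by the median b = 0 signal in the prostate
#'
#' Every voxel's signal at every b-value is divided by the median b = 0
#' signal over the prostate mask, putting the series into normalized units
#' in which the fitted compartment contributions are comparable across
#' patients.
#'
#' @param series A [dwi_series()].
#' @param prostate_mask Logical 3-D array matching the series grid.
#' @return The normalized [dwi_series()] (`normalized = TRUE`).
#' @export
normalize_by_median_b0 <- function(series, prostate_mask) {
  stopifnot(inherits(series, "dwi_series"))
  b0_idx <- which(series$b_values == 0)
  if (length(b0_idx) == 0L) stop("series has no b = 0 volume")
  if (!any(prostate_mask)) stop("prostate mask is empty")
  b0 <- series$signal[, , , b0_idx[1], drop = FALSE]
  m <- stats::median(b0[prostate_mask])
  if (!is.finite(m) || m <= 0) {
    stop("median b = 0 signal within the mask is not positive; cannot normalize")
  }
  dwi_series(series$signal / m, series$b_values, series$voxel_size_mm,
             normalized = TRUE)
}

# Exact nonnegative least squares for the 4-column decay design, vectorized
# over voxels by support enumeration: with 4 coefficients there are 15
# nonempty supports; each support's unconstrained least-squares solution is
# obtained for all voxels at once by a precomputed pseudoinverse, and the
# feasible (all-nonnegative) candidate with the smallest residual is the
# global NNLS optimum (at the optimum, the positive coefficients solve the
# unconstrained normal equations on their support).
# S: n_b x n_vox matrix. Returns list(coef = 4 x n_vox, rss = n_vox).
nnls_enumerate <- function(A, S, tol = 1e-10) {
  n_vox <- ncol(S)
  p <- ncol(A)
  best_coef <- matrix(0, p, n_vox)
  best_rss <- colSums(S^2)                       # empty support: C = 0
  supports <- lapply(seq_len(2^p - 1L), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  for (J in supports) {
    AJ <- A[, J, drop = FALSE]
    PJ <- solve(crossprod(AJ), t(AJ))            # |J| x n_b
    cj <- PJ %*% S                               # |J| x n_vox
    feasible <- colSums(cj < -tol) == 0L
    if (!any(feasible)) next
    cj[cj < 0] <- 0
    resid <- AJ %*% cj - S
    rss <- colSums(resid^2)
    better <- feasible & (rss < best_rss - 1e-15)
    if (any(better)) {
      best_rss[better] <- rss[better]
      best_coef[, better] <- 0
      best_coef[J, better] <- cj[, better]
    }
  }
  list(coef = best_coef, rss = best_rss)
}

#' Fit the four-compartment decay model per voxel
#'
#' For each masked voxel, solves the nonnegative least-squares problem
#' `min || A C - S ||_2, C >= 0`, where A is the compartmental decay design
#' ([decay_design_matrix()]) and S the normalized signal across b-values.
#' Nonnegativity reflects the interpretation of C1..C4 as signal
#' contributions of physical tissue compartments; an unconstrained ordinary
#' least-squares fit is available via `nonneg = FALSE` for comparison.
#' Voxels outside the mask are set to `NA` and excluded from all downstream
#' reductions.
#'
#' @param series A normalized [dwi_series()] (>= 4 b-values).
#' @param mask Logical 3-D array of voxels to fit.
#' @param nonneg Constrain coefficients to be nonnegative (default `TRUE`).
#' @return Object of class `compartment_maps`: list with `c` (4-D array,
#'   4th dimension the compartment), `residual_rms` (3-D array),
#'   `b_values`, `voxel_size_mm`.
#' @export
fit_compartments <- function(series, mask, nonneg = TRUE) {
  stopifnot(inherits(series, "dwi_series"))
  if (!series$normalized) {
    stop("series must be normalized (normalize_by_median_b0) before fitting")
  }
  if (length(series$b_values) < 4L) stop("need >= 4 b-values to fit 4 compartments")
  dims <- dim(series$signal)[1:3]
  idx <- which(mask)
  S <- t(matrix(series$signal, prod(dims), dim(series$signal)[4])[idx, , drop = FALSE])
  A <- decay_design_matrix(series$b_values)
  if (nonneg) {
    fit <- nnls_enumerate(A, S)
  } else {
    coef <- solve(crossprod(A), t(A)) %*% S
    fit <- list(coef = coef, rss = colSums((A %*% coef - S)^2))
  }
  cmaps <- array(NA_real_, c(dims, 4L))
  flat <- matrix(NA_real_, prod(dims), 4L)
  flat[idx, ] <- t(fit$coef)
  cmaps[] <- flat
  rms <- array(NA_real_, dims)
  rms[idx] <- sqrt(fit$rss / length(series$b_values))
  structure(
    list(c = cmaps, residual_rms = rms, b_values = series$b_values,
         voxel_size_mm = series$voxel_size_mm, nonneg = nonneg),
    class = "compartment_maps"
  )
}

#' RSI restriction score map
#'
#' The restriction score is the fitted contribution of the slowest
#' ("restricted intracellular") compartment, i.e. the C1 map of the
#' four-compartment fit, in median-b0-normalized units. It is returned
#' voxelwise, with `NA` outside the fitted mask.
#'
#' @param maps A [fit_compartments()] result.
#' @return Object of class `rsirs_map`: list with `value` (3-D array) and
#'   `voxel_size_mm`.
#' @export
compute_rsirs <- function(maps) {
  stopifnot(inherits(maps, "compartment_maps"))
  structure(
    list(value = maps$c[, , , 1L], voxel_size_mm = maps$voxel_size_mm),
    class = "rsirs_map"
  )
}
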
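#' Design matrix of compartmental exponential decays
#'
#' Builds the n_b x 4 matrix A with A[j, i] = exp(-b_j * D_i) for the three
#' finite-coefficient compartments (restricted, hindered, free). The vascular
#' flow compartment decays much faster than 3.0e-3 mm^2/s, so
#' exp(-b * D_flow) is numerically zero at every nonzero b of the protocol;
#' its column is the b = 0 indicator, which keeps the design well conditioned
#' while being indistinguishable from any sufficiently large coefficient.
#'
#' @param b_values Numeric vector of b-values (s/mm^2).
#' @param diffusion_coeffs Length-3 numeric vector of compartment ADCs
#'   (mm^2/s); defaults to [rsi_diffusion_coeffs()].
#' @return Numeric matrix, `length(b_values)` rows, 4 columns
#'   (restricted, hindered, free, flow).
#' @export
#' @examples
#' decay_design_matrix(c(0, 500, 1000, 2000))
decay_design_matrix <- function(b_values, diffusion_coeffs = rsi_diffusion_coeffs()) {
  b_values <- as.numeric(b_values)
  stopifnot(length(diffusion_coeffs) == 3L)
  A <- cbind(
    exp(-b_values %o% diffusion_coeffs),
    as.numeric(b_values == 0)
  )
  colnames(A) <- c(names(diffusion_coeffs), "flow")
  rownames(A) <- paste0("b", b_values)
  A
}

#' Simulate the diffusion signal of one voxel
#'
#' Forward model: the noiseless signal at b-value b is the linear combination
#' sum_i C_i exp(-b D_i) of the four compartment decays (flow contributing at
#' b = 0 only). Magnitude (Rician) noise is applied independently per b-value
#' when `noise_sigma > 0`: the output is |S + sigma (Z1 + i Z2)| with
#' independent standard normal Z1, Z2, i.e. the magnitude of a complex
#' Gaussian centered on the true signal.
#'
#' Draws use the current R random number generator state; seed upstream for
#' reproducibility.
#'
#' @param fractions Nonnegative 4-vector of compartment contributions
#'   (C1..C4, normalized units).
#' @param protocol An [acquisition_protocol()].
#' @param noise_sigma Rician noise scale per channel, normalized units, >= 0.
#' @return Numeric vector of signals, one per b-value.
#' @export
#' @examples
#' p <- acquisition_protocol()
#' simulate_voxel_signal(c(1, 0, 0, 0), p)        # pure restricted decay
simulate_voxel_signal <- function(fractions, protocol, noise_sigma = 0) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 4L || any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("fractions must be a nonnegative finite 4-vector")
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be nonnegative")
  }
  A <- decay_design_matrix(protocol$b_values)
  s <- drop(A %*% fractions)
  if (noise_sigma > 0) {
    n <- length(s)
    s <- sqrt((s + stats::rnorm(n, sd = noise_sigma))^2 +
                stats::rnorm(n, sd = noise_sigma)^2)
  }
  unname(s)
}

# Vectorized forward model + Rician noise over a matrix of fraction rows.
# frac_mat: n_vox x 4; returns n_vox x n_b signal matrix.
simulate_signal_matrix <- function(frac_mat, b_values, noise_sigma) {
  A <- decay_design_matrix(b_values)
  s <- frac_mat %*% t(A)
  if (noise_sigma > 0) {
    s <- sqrt((s + stats::rnorm(length(s), sd = noise_sigma))^2 +
                matrix(stats::rnorm(length(s), sd = noise_sigma), nrow(s))^2)
  }
  s
}
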
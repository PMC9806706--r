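# Shared fixtures and independent oracles for the test suite.

# Build a tiny dwi_series from a voxel-by-b matrix of signals laid out on a
# small grid (remaining voxels get `fill`).
tiny_series <- function(signal_rows, b_values = c(0, 500, 1000, 2000),
                        grid = c(4, 4, 3), fill = 1,
                        voxel_size_mm = c(2.5, 2.5, 6), normalized = FALSE) {
  n_b <- length(b_values)
  arr <- array(fill, c(grid, n_b))
  flat <- matrix(arr, prod(grid), n_b)
  flat[seq_len(nrow(signal_rows)), ] <- signal_rows
  arr[] <- flat
  dwi_series(arr, b_values, voxel_size_mm, normalized = normalized)
}

first_voxels_mask <- function(n, grid = c(4, 4, 3)) {
  m <- array(FALSE, grid)
  m[seq_len(n)] <- TRUE
  m
}

# Analytic mean of a Rice(A, sigma) magnitude via the Laguerre half-integer
# polynomial and modified Bessel functions.
rice_mean <- function(A, sigma) {
  x <- A^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) * exp(-x / 2) *
    ((1 + x) * besselI(x / 2, 0) + x * besselI(x / 2, 1))
}

# Exhaustive pairwise-counting AUC: wins + half-ties over all pos/neg pairs.
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Independent NNLS oracle (Lawson-Hanson via pracma) for one voxel.
oracle_nnls <- function(A, s) {
  as.numeric(pracma::lsqnonneg(A, s)$x)
}
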
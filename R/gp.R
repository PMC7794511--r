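#' Exponentiated-quadratic Gaussian-process covariance
#'
#' Spatial covariance between grid-cell centroids,
#' \eqn{k(d) = \sigma^2 \exp(-d^2 / (2 \ell^2))} on raw (unscaled) metre
#' coordinates, plus a small diagonal jitter proportional to \eqn{\sigma^2}
#' for numerical positive-definiteness.
#'
#' @param coords numeric matrix, one row per cell, columns x and y (m).
#' @param gp_sd marginal standard deviation (log-odds units), >= 0.
#' @param gp_lengthscale length-scale in metres, > 0.
#' @param jitter relative diagonal jitter (multiplied by `gp_sd^2`).
#' @return covariance matrix.
#' @export
gp_covariance <- function(coords, gp_sd, gp_lengthscale, jitter = 1e-8) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, gp_sd >= 0, gp_lengthscale > 0, jitter >= 0)
  d2 <- as.matrix(stats::dist(coords))^2
  K <- gp_sd^2 * exp(-d2 / (2 * gp_lengthscale^2))
  K + diag(jitter * gp_sd^2, nrow(K))
}

# unit-variance kernel matrix (no amplitude, no jitter)
gp_kernel_unit <- function(coords, gp_lengthscale) {
  d2 <- as.matrix(stats::dist(as.matrix(coords)))^2
  exp(-d2 / (2 * gp_lengthscale^2))
}

# Lower Cholesky factor with escalating diagonal jitter.  Starts at `jitter0`
# and multiplies by 10 up to `jitter_max`; beyond that the decomposition is
# reported as failed, naming `label` and the last jitter tried.
chol_spd <- function(K, jitter0 = 1e-8, jitter_max = 1e-4, label = "matrix") {
  jit <- jitter0
  repeat {
    ch <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(ch)) return(list(L = t(ch), jitter = jit))
    if (jit >= jitter_max)
      stop(sprintf(
        "Cholesky factorization failed for %s (last jitter tried: %g)",
        label, jit))
    jit <- jit * 10
  }
}
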
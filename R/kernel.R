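#' Exponentiated-quadratic kernel on isotype-count distances
#'
#' Builds the covariance matrix of the Gaussian-process offset:
#' `K[i, j] = eta_sq * exp(-(rho_sq / 2) * (igg_i - igg_j)^2)`, with `jitter`
#' added to the diagonal for numerical stability. `eta_sq` is the maximum
#' covariance between cells (attained at zero distance) and `rho_sq` sets how
#' fast covariance decays as two cells' isotype control counts diverge.
#' Distances are taken on the raw counts.
#'
#' @param igg nonnegative integer vector of isotype control counts (length
#'   >= 2).
#' @param eta_sq positive real, maximum covariance.
#' @param rho_sq nonnegative real, decay rate.
#' @param jitter nonnegative diagonal jitter; default `1e-6 * eta_sq`.
#' @return An object of class `kernel_matrix`: list with the matrix `K` and
#'   the parameters used.
#' @examples
#' k <- build_kernel(c(0, 1), eta_sq = 1, rho_sq = 2, jitter = 0)
#' k$K[1, 2]  # exp(-1)
#' @export
build_kernel <- function(igg, eta_sq, rho_sq, jitter = 1e-6 * eta_sq) {
  if (!is.numeric(igg) || length(igg) < 2 || !is_count_vector(igg)) {
    adtgp_error("igg must be a nonnegative integer vector of length >= 2",
                "adtgp_error_invalid_parameter")
  }
  for (v in list(eta_sq = eta_sq, rho_sq = rho_sq, jitter = jitter)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      adtgp_error("kernel parameters must be single finite numbers",
                  "adtgp_error_invalid_parameter")
    }
  }
  if (eta_sq <= 0 || rho_sq < 0 || jitter < 0) {
    adtgp_error("need eta_sq > 0, rho_sq >= 0, jitter >= 0",
                "adtgp_error_invalid_parameter")
  }
  d2 <- outer(as.numeric(igg), as.numeric(igg), "-")^2
  K <- eta_sq * exp(-rho_sq / 2 * d2)
  K <- (K + t(K)) / 2
  diag(K) <- eta_sq + jitter
  structure(list(K = K, eta_sq = eta_sq, rho_sq = rho_sq, jitter = jitter),
            class = "kernel_matrix")
}

# Lower Cholesky factor of K (+ escalating jitter). The jitter is doubled up
# to `max_tries - 1` times on failure before raising, and the jitter actually
# used is reported in the error.
chol_lower <- function(K, jitter, max_tries = 4L) {
  n <- nrow(K)
  K0 <- K
  diag(K0) <- diag(K) - jitter   # re-apply jitter explicitly below
  for (t in seq_len(max_tries)) {
    R <- tryCatch(chol(K0 + diag(jitter, n)), error = function(e) NULL)
    if (!is.null(R)) return(list(L = t(R), jitter = jitter))
    jitter <- if (jitter > 0) jitter * 2 else 1e-8 * mean(diag(K0))
  }
  adtgp_error(sprintf(
    "Cholesky factorization failed even with diagonal jitter %.3g", jitter),
    "adtgp_error_numerical_instability")
}
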
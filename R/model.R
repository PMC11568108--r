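#' Negative binomial (NB2) log probability mass
#'
#' Log pmf of the negative binomial in its mean/overdispersion (NB2)
#' parameterization: mean `mu`, variance `mu + mu^2/phi`. This is the
#' observation model for the raw ADT counts; small `phi` means heavy
#' overdispersion, `phi -> Inf` recovers the Poisson.
#'
#' @param y nonnegative integer count (vectorized).
#' @param mu positive mean.
#' @param phi positive overdispersion.
#' @return log probability mass, vectorized over the inputs.
#' @examples
#' nb_logpmf(0, mu = 20, phi = 5)  # phi * (log phi - log(phi + mu))
#' @export
nb_logpmf <- function(y, mu, phi) {
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    adtgp_error("y must be nonnegative integer", "adtgp_error_domain")
  }
  if (any(mu <= 0) || any(phi <= 0) || any(!is.finite(mu)) || any(!is.finite(phi))) {
    adtgp_error("need mu > 0 and phi > 0", "adtgp_error_domain")
  }
  stats::dnbinom(y, size = phi, mu = mu, log = TRUE)
}

#' Linear predictor of the count model
#'
#' Evaluates the log-mean `log(mu_i) = mu0 + gamma_i + sum_k beta_k[X_ki]` for
#' every cell: intercept plus the per-cell Gaussian-process offset plus one
#' coefficient per categorical covariate level. Level 1 of every covariate
#' carries coefficient 0 by the package's identifiability convention, so
#' `betas` vectors start with 0 in their first position.
#'
#' @param design an [adt_design()] (or coercible data frame).
#' @param mu0 intercept (real).
#' @param betas named list, one numeric vector per non-intercept design
#'   column, giving the coefficient for each occupied level of that column.
#'   Empty list for an intercept-only design.
#' @param gamma per-cell offset vector (real, one per row of `design`), or a
#'   single 0 to mean "no offset".
#' @return numeric vector of `log(mu_i)`.
#' @examples
#' d <- adt_design(data.frame(mu0 = 1, T = c(1, 1, 2, 2)))
#' linear_predictor(d, mu0 = 2, betas = list(T = c(0, 0.5)), gamma = 0)
#' @export
linear_predictor <- function(design, mu0, betas = list(), gamma = 0) {
  design <- if (inherits(design, "adt_design")) design else adt_design(design)
  n <- nrow(design)
  if (length(gamma) == 1) gamma <- rep(gamma, n)
  if (length(gamma) != n) {
    adtgp_error("gamma must have one entry per cell", "adtgp_error_design_mismatch")
  }
  eta <- rep(mu0, n) + gamma
  for (j in names(design)[-1]) {
    b <- betas[[j]]
    if (is.null(b)) {
      adtgp_error(sprintf("no coefficients supplied for covariate '%s'", j),
                  "adtgp_error_design_mismatch")
    }
    lev <- design[[j]]
    if (any(lev < 1) || any(lev > length(b))) {
      adtgp_error(sprintf("level code out of range for covariate '%s'", j),
                  "adtgp_error_design_mismatch")
    }
    eta <- eta + b[lev]
  }
  eta
}

# log MVN(0, K) density of g given the lower Cholesky factor L of K
mvn_logpdf_chol <- function(g, L) {
  w <- forwardsolve(L, g)
  -sum(log(diag(L))) - 0.5 * sum(w^2) - length(g) / 2 * log(2 * pi)
}

# log density of the truncated-normal eta_sq prior (truncated to (0, Inf))
etasq_logprior <- function(eta_sq, loc, scale) {
  if (eta_sq <= 0) return(-Inf)
  stats::dnorm(eta_sq, loc, scale, log = TRUE) -
    stats::pnorm(0, loc, scale, lower.tail = FALSE, log.p = TRUE)
}

#' Joint log density of data and parameters
#'
#' Log prior + log Gaussian-process density of the offset + negative-binomial
#' log likelihood, the (unnormalized) posterior kernel that MCMC explores.
#' The Gaussian-process offset `gamma` has density MVN(0, K) with K from
#' [build_kernel()] evaluated on the isotype counts. Parameters outside the
#' prior support (e.g. `rho_sq` beyond its uniform bounds) give `-Inf`.
#'
#' @param protein nonnegative integer count vector for the target antibody.
#' @param igg nonnegative integer isotype control counts, same cells.
#' @param design an [adt_design()].
#' @param params list with elements `mu0`, `phi`, `eta_sq`, `rho_sq`, `betas`
#'   (as in [linear_predictor()]) and `gamma` (per-cell offset).
#' @param priors an [adtgp_priors()].
#' @param jitter diagonal jitter for the kernel; default `1e-6 * eta_sq`.
#' @return single real, the joint log density.
#' @export
joint_log_density <- function(protein, igg, design, params,
                              priors = adtgp_priors(),
                              jitter = 1e-6 * params$eta_sq) {
  design <- if (inherits(design, "adt_design")) design else adt_design(design)
  n <- nrow(design)
  if (length(protein) != n || length(igg) != n) {
    adtgp_error("protein, igg and design must describe the same cells",
                "adtgp_error_design_mismatch")
  }
  p <- params
  if (p$mu0 <= 0 || p$phi <= 0 || p$eta_sq <= 0) return(-Inf)
  if (p$rho_sq < priors$rhosq_lo || p$rho_sq > priors$rhosq_hi) return(-Inf)
  lp <- stats::dgamma(p$mu0, priors$mu0_shape, priors$mu0_rate, log = TRUE) +
    stats::dgamma(p$phi, priors$phi_shape, priors$phi_rate, log = TRUE) +
    etasq_logprior(p$eta_sq, priors$etasq_loc, priors$etasq_scale) +
    stats::dunif(p$rho_sq, priors$rhosq_lo, priors$rhosq_hi, log = TRUE)
  for (j in names(design)[-1]) {
    b <- p$betas[[j]]
    if (length(b) > 1) {
      lp <- lp + sum(stats::dnorm(b[-1], priors$beta_loc, priors$beta_scale,
                                  log = TRUE))
    }
  }
  k <- build_kernel(igg, p$eta_sq, p$rho_sq, jitter = jitter)
  L <- chol_lower(k$K, k$jitter)$L
  lp <- lp + mvn_logpdf_chol(p$gamma, L)
  eta <- linear_predictor(design, p$mu0, p$betas, p$gamma)
  lp + sum(nb_logpmf(protein, exp(eta), p$phi))
}
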
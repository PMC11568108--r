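# independent NB2 oracle: direct log-gamma evaluation of the pmf
nb2_logpmf_oracle <- function(y, mu, phi) {
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    phi * (log(phi) - log(phi + mu)) + y * (log(mu) - log(phi + mu))
}

test_that("nb_logpmf matches the log-gamma oracle and normalizes", {
  grid <- expand.grid(y = c(0L, 1L, 3L, 17L, 200L),
                      mu = c(0.5, 5, 20, 200),
                      phi = c(0.3, 1, 5, 50))
  got <- with(grid, nb_logpmf(y, mu, phi))
  want <- with(grid, nb2_logpmf_oracle(y, mu, phi))
  expect_lt(max(abs(got - want)), 1e-10)
  # truncated sum over the support is 1
  expect_equal(sum(exp(nb_logpmf(0:10000, 20, 5))), 1, tolerance = 1e-10)
  expect_equal(sum(exp(nb_logpmf(0:10000, 200, 1))), 1, tolerance = 1e-8)
  # closed form at zero
  expect_equal(nb_logpmf(0, 20, 5), 5 * (log(5) - log(25)), tolerance = 1e-12)
})

test_that("NB2 moments: variance is mu + mu^2/phi", {
  with_restored_rng(42, {
    x <- rnbinom(2e5, size = 1, mu = 200)
    se_mean <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 200), 3 * se_mean)
    # SE of the sample variance from empirical fourth moment
    m <- mean(x)
    m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
    se_var <- sqrt((m4 - m2^2 * (length(x) - 3) / (length(x) - 1)) / length(x))
    expect_lt(abs(var(x) - (200 + 200^2 / 1)), 3 * se_var)
  })
})

test_that("linear predictor adds intercept, level coefficients and offset", {
  d0 <- adt_design(data.frame(mu0 = rep(1, 4)))
  expect_equal(linear_predictor(d0, mu0 = 3, gamma = 0), rep(3, 4))
  d <- two_group_design(2)
  lp <- linear_predictor(d, mu0 = 2, betas = list(T = c(0, 0.5)), gamma = 0)
  expect_equal(lp, c(2, 2, 2.5, 2.5))
  d2 <- adt_design(data.frame(mu0 = c(1, 1)))
  expect_equal(linear_predictor(d2, mu0 = 0, gamma = c(0.1, -0.1)), c(0.1, -0.1))
  # level code outside the coefficient range
  expect_error(linear_predictor(d, mu0 = 0, betas = list(T = c(0)), gamma = 0),
               class = "adtgp_error_design_mismatch")
})

test_that("joint log density equals an independently assembled sum", {
  skip_if_not_installed("mvtnorm")
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(3:5, 1)
    protein <- rnbinom(n, mu = 30, size = 2)
    igg <- rnbinom(n, mu = 20, size = 5)
    d <- adt_design(data.frame(mu0 = 1, T = c(rep(1, n - 1), 2)))
    pri <- adtgp_priors(rhosq_hi = 0.05)
    params <- list(mu0 = runif(1, 1, 4), phi = runif(1, 0.5, 5),
                   eta_sq = runif(1, 0.5, 3), rho_sq = runif(1, 0, 0.05),
                   betas = list(T = c(0, rnorm(1))), gamma = rnorm(n, 0, 0.3))
    jitter <- 1e-6 * params$eta_sq
    got <- joint_log_density(protein, igg, d, params, pri, jitter = jitter)
    # oracle: each term coded separately
    K <- params$eta_sq * exp(-params$rho_sq / 2 * outer(igg, igg, "-")^2)
    diag(K) <- diag(K) + jitter
    lp_mean <- params$mu0 + params$gamma +
      params$betas$T[d$T]
    want <- dgamma(params$mu0, 7, 2, log = TRUE) +
      dgamma(params$phi, 0.5, 0.5, log = TRUE) +
      (dnorm(params$eta_sq, 2, 1, log = TRUE) -
         pnorm(0, 2, 1, lower.tail = FALSE, log.p = TRUE)) +
      dunif(params$rho_sq, 0, 0.05, log = TRUE) +
      dnorm(params$betas$T[2], 0, 1, log = TRUE) +
      mvtnorm::dmvnorm(params$gamma, sigma = K, log = TRUE) +
      sum(dnbinom(protein, size = params$phi, mu = exp(lp_mean), log = TRUE))
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("joint log density respects the rho_sq prior support", {
  n <- 3
  protein <- c(1L, 5L, 2L); igg <- c(10L, 20L, 30L)
  d <- adt_design(data.frame(mu0 = rep(1, n)))
  pri <- adtgp_priors(rhosq_hi = 1)
  params <- list(mu0 = 2, phi = 1, eta_sq = 1, rho_sq = 2,
                 betas = list(), gamma = rep(0, n))
  expect_identical(joint_log_density(protein, igg, d, params, pri), -Inf)
  # at gamma = 0 the MVN term is the log normalizing constant of N(0, K)
  params$rho_sq <- 0.5
  k <- build_kernel(igg, 1, 0.5)
  L <- adtgp:::chol_lower(k$K, k$jitter)$L
  const <- -sum(log(diag(L))) - n / 2 * log(2 * pi)
  base <- joint_log_density(protein, igg, d, params, pri)
  no_mvn <- dgamma(2, 7, 2, log = TRUE) + dgamma(1, 0.5, 0.5, log = TRUE) +
    (dnorm(1, 2, 1, log = TRUE) - pnorm(0, 2, 1, lower.tail = FALSE, log.p = TRUE)) +
    dunif(0.5, 0, 1, log = TRUE) +
    sum(dnbinom(protein, size = 1, mu = exp(2), log = TRUE))
  expect_equal(base - no_mvn, const, tolerance = 1e-10)
})
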
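# Model fitting by MCMC.
#
# The posterior is explored with a composite Markov-chain scan built for the
# geometry of this model (a latent Gaussian field under a count likelihood):
#
#   1. elliptical slice sampling of the whitened GP offset, run blockwise in
#      the kernel eigenbasis — the likelihood-pinned smooth modes and the
#      nearly-free rough modes are rotated separately, then jointly, so the
#      field's amplitude decorrelates quickly;
#   2. univariate slice sampling of mu0, each free level coefficient and phi;
#   3. interweaved centered/whitened (ASIS) slice updates of the kernel
#      hyperparameters eta_sq and rho_sq — eta_sq is a pure scale parameter,
#      so its centered conditional needs no refactorization;
#   4. "ridge" slice moves that shift mu0 (or a level coefficient) together
#      with a kernel-smoothed compensating shift of the offset field, the
#      direction the likelihood cannot see but the priors trade off along.
#
# Every update is a valid MCMC kernel (slice sampling or
# Metropolis-within-Gibbs), so the scan targets the exact joint posterior of
# joint_log_density(). All randomness flows from per-chain seeds derived
# from the user seed; fits are bit-reproducible.

# univariate slice sampler (Neal 2003: stepping out + shrinkage)
slice_sample1 <- function(x0, logf, w = 1, m = 30, lower = -Inf, upper = Inf) {
  f0 <- logf(x0)
  if (!is.finite(f0)) {
    adtgp_error("slice sampler started at a zero-density point",
                "adtgp_error_numerical_instability")
  }
  y <- f0 + log(stats::runif(1))
  u <- stats::runif(1)
  lft <- x0 - w * u
  rgt <- lft + w
  j <- floor(m * stats::runif(1))
  k <- m - 1 - j
  while (j > 0 && lft > lower && logf(lft) > y) { lft <- lft - w; j <- j - 1 }
  while (k > 0 && rgt < upper && logf(rgt) > y) { rgt <- rgt + w; k <- k - 1 }
  lft <- max(lft, lower); rgt <- min(rgt, upper)
  repeat {
    x1 <- stats::runif(1, lft, rgt)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) lft <- x1 else rgt <- x1
  }
}

# one chain of the sampler; returns kept draws
run_chain <- function(y, igg, X, lev_names, priors, iter_warmup, iter_sampling,
                      seed, rho_fixed) {
  set.seed(seed)
  n <- length(y)
  D2 <- outer(as.numeric(igg), as.numeric(igg), "-")^2
  nb <- length(lev_names)                  # free coefficients
  # indicator vectors for each free coefficient
  ind <- lapply(seq_len(nb), function(k) as.numeric(X[, k]))
  rho_lo <- priors$rhosq_lo; rho_hi <- priors$rhosq_hi
  corr_mat <- function(rho2) exp(-rho2 / 2 * D2) + diag(1e-4, n)

  # initial state
  mu0 <- max(log(mean(y) + 1), 0.1)
  phi <- 1
  eta2 <- max(priors$etasq_loc, 0.5)
  rho2 <- if (rho_fixed) rho_lo else rho_lo + 0.5 * (rho_hi - rho_lo)
  beta <- rep(0, nb)
  eig <- eigen(corr_mat(rho2), symmetric = TRUE)
  lam <- pmax(eig$values, 1e-12); U <- eig$vectors
  x <- stats::rnorm(n) * 0.1
  gam_of <- function(x, eta2) sqrt(eta2) * as.vector(U %*% (sqrt(lam) * x))
  gam <- gam_of(x, eta2)

  fixed_eff <- function(beta) {
    fe <- rep(mu0, n)
    for (k in seq_len(nb)) fe <- fe + beta[k] * ind[[k]]
    fe
  }
  loglik <- function(mu0, beta, gam, phi) {
    fe <- rep(mu0, n)
    for (k in seq_len(nb)) fe <- fe + beta[k] * ind[[k]]
    sum(stats::dnbinom(y, size = phi, mu = exp(fe + gam), log = TRUE))
  }
  chol_logq <- function(rho2, gam) {
    R <- chol(corr_mat(rho2))
    c(-sum(log(diag(R))), sum(forwardsolve(t(R), gam)^2))
  }
  lp_eta <- function(e) stats::dnorm(e, priors$etasq_loc, priors$etasq_scale, log = TRUE)
  ll <- loglik(mu0, beta, gam, phi)

  keep <- list(mu0 = numeric(iter_sampling), phi = numeric(iter_sampling),
               eta_sq = numeric(iter_sampling), rho_sq = numeric(iter_sampling),
               beta = matrix(NA_real_, iter_sampling, nb,
                             dimnames = list(NULL, lev_names)),
               gamma = matrix(NA_real_, iter_sampling, n))
  tot <- iter_warmup + iter_sampling

  for (it in seq_len(tot)) {
    ## 1. block elliptical slice sampling of the whitened field.
    ##    "pinned" modes are those whose prior field amplitude sqrt(eta2*lam)
    ##    exceeds what the likelihood can distinguish (~0.02 on the log-mean);
    ##    the rest rotate nearly freely, so splitting them off lets the
    ##    field's amplitude decorrelate quickly.
    pinned <- eta2 * lam > 4e-4
    if (sum(pinned) > 40L) pinned <- seq_along(lam) <= 40L
    blocks <- if (all(pinned) || !any(pinned)) list(rep(TRUE, n))
              else list(pinned, !pinned, rep(TRUE, n))
    for (blk in blocks) {
      nu <- stats::rnorm(n); nu[!blk] <- 0
      thr <- ll + log(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi); th_min <- th - 2 * pi; th_max <- th
      repeat {
        xp <- x
        xp[blk] <- x[blk] * cos(th) + nu[blk] * sin(th)
        gp <- gam_of(xp, eta2)
        llp <- loglik(mu0, beta, gp, phi)
        if (llp > thr) { x <- xp; gam <- gp; ll <- llp; break }
        if (th < 0) th_min <- th else th_max <- th
        th <- stats::runif(1, th_min, th_max)
      }
    }
    ## 1b. per-mode slice updates of the leading (likelihood-pinned) modes:
    ##     rank-1 changes of the field, so each evaluation is cheap
    se <- sqrt(eta2)
    for (j in seq_len(min(sum(pinned), 40L))) {
      uj <- se * sqrt(lam[j]) * U[, j]
      xj <- x[j]
      gbase <- gam - xj * uj
      x[j] <- slice_sample1(xj, function(v)
        loglik(mu0, beta, gbase + v * uj, phi) - 0.5 * v^2, w = 1)
      gam <- gbase + x[j] * uj
    }
    ll <- loglik(mu0, beta, gam, phi)
    ## 2. scalar slice updates
    mu0 <- slice_sample1(mu0, function(v)
      loglik(v, beta, gam, phi) +
        stats::dgamma(v, priors$mu0_shape, priors$mu0_rate, log = TRUE),
      w = 0.5, lower = 1e-10)
    for (k in seq_len(nb)) {
      beta[k] <- slice_sample1(beta[k], function(v) {
        b <- beta; b[k] <- v
        loglik(mu0, b, gam, phi) +
          stats::dnorm(v, priors$beta_loc, priors$beta_scale, log = TRUE)
      }, w = 0.5)
    }
    phi <- exp(slice_sample1(log(phi), function(v)
      loglik(mu0, beta, gam, exp(v)) +
        stats::dgamma(exp(v), priors$phi_shape, priors$phi_rate, log = TRUE) + v,
      w = 1))
    ll <- loglik(mu0, beta, gam, phi)
    ## 3. kernel hyperparameters, interweaved centered/whitened
    # eta_sq centered: gamma fixed; q = eta2 |x|^2, no refactorization needed
    q <- eta2 * sum(x^2)
    le <- slice_sample1(log(eta2), function(v) {
      e <- exp(v)
      -n / 2 * v - 0.5 * q / e + lp_eta(e) + v
    }, w = 1.5)
    x <- x * sqrt(eta2 / exp(le)); eta2 <- exp(le)
    # eta_sq whitened: x fixed, likelihood-informed
    g0 <- gam / sqrt(eta2)
    le <- slice_sample1(log(eta2), function(v) {
      e <- exp(v)
      loglik(mu0, beta, sqrt(e) * g0, phi) + lp_eta(e) + v
    }, w = 1)
    eta2 <- exp(le); gam <- sqrt(eta2) * g0
    if (!rho_fixed) for (round in 1:2) {
      wid <- rho_hi - rho_lo
      # rho_sq centered (gamma fixed), on the logit of its uniform support
      lr <- slice_sample1(stats::qlogis((rho2 - rho_lo) / wid), function(v) {
        r <- rho_lo + stats::plogis(v) * wid
        cq <- chol_logq(r, gam)
        cq[1] - 0.5 * cq[2] / eta2 + log(r - rho_lo) + log(1 - (r - rho_lo) / wid)
      }, w = 2)
      rho2 <- rho_lo + stats::plogis(lr) * wid
      # rho_sq whitened (Cholesky coordinates fixed, likelihood-informed)
      zch <- forwardsolve(t(chol(corr_mat(rho2))), gam) / sqrt(eta2)
      lr <- slice_sample1(stats::qlogis((rho2 - rho_lo) / wid), function(v) {
        r <- rho_lo + stats::plogis(v) * wid
        Lv <- t(chol(corr_mat(r)))
        loglik(mu0, beta, sqrt(eta2) * as.vector(Lv %*% zch), phi) +
          log(r - rho_lo) + log(1 - (r - rho_lo) / wid)
      }, w = 2)
      rho2 <- rho_lo + stats::plogis(lr) * wid
      gam <- sqrt(eta2) * as.vector(t(chol(corr_mat(rho2))) %*% zch)
      # refresh the eigenbasis and whitened coordinates
      eig <- eigen(corr_mat(rho2), symmetric = TRUE)
      lam <- pmax(eig$values, 1e-12); U <- eig$vectors
      x <- as.vector(crossprod(U, gam)) / (sqrt(lam) * sqrt(eta2))
    }
    ## 4. ridge moves: intercept/coefficient vs. smoothed field shift
    se <- sqrt(eta2)
    mu_cur <- exp(fixed_eff(beta) + gam)
    info <- mean(phi * mu_cur / (phi + mu_cur))
    delta <- 1 / max(info, 1e-3)
    shrink <- lam / (lam + delta)
    smooth_dir <- function(u) as.vector(U %*% (shrink * as.vector(crossprod(U, u))))
    xshift <- function(v) as.vector(crossprod(U, v)) / (sqrt(lam) * se)
    v1 <- smooth_dir(rep(1, n)); w1 <- xshift(v1)
    d <- slice_sample1(0, function(d) {
      if (mu0 + d <= 0) return(-Inf)
      loglik(mu0 + d, beta, gam - d * v1, phi) +
        stats::dgamma(mu0 + d, priors$mu0_shape, priors$mu0_rate, log = TRUE) -
        0.5 * sum((x - d * w1)^2)
    }, w = 1)
    mu0 <- mu0 + d; x <- x - d * w1; gam <- gam - d * v1
    for (k in seq_len(nb)) {
      vk <- smooth_dir(ind[[k]]); wk <- xshift(vk)
      d <- slice_sample1(0, function(d) {
        b <- beta; b[k] <- b[k] + d
        loglik(mu0, b, gam - d * vk, phi) +
          stats::dnorm(b[k], priors$beta_loc, priors$beta_scale, log = TRUE) -
          0.5 * sum((x - d * wk)^2)
      }, w = 1)
      beta[k] <- beta[k] + d; x <- x - d * wk; gam <- gam - d * vk
    }
    ll <- loglik(mu0, beta, gam, phi)

    if (it > iter_warmup) {
      i <- it - iter_warmup
      keep$mu0[i] <- mu0; keep$phi[i] <- phi
      keep$eta_sq[i] <- eta2; keep$rho_sq[i] <- rho2
      if (nb > 0) keep$beta[i, ] <- beta
      keep$gamma[i, ] <- gam
    }
  }
  keep
}

#' Fit the Gaussian-process count model
#'
#' Fits the negative-binomial regression with a Gaussian-process per-cell
#' offset learned from isotype control counts, by MCMC (a composite scan of
#' elliptical slice sampling on the latent field and slice updates of the
#' scalar parameters; see the package vignette for the scheme and its
#' rationale). Returns posterior draws for every model parameter together
#' with conditional predictive count samples for every combination of
#' covariate levels — the distribution of protein expression given equal
#' isotype control noise across cells.
#'
#' @param protein nonnegative integer counts of the target antibody, one per
#'   cell.
#' @param igg nonnegative integer isotype control counts, same cells. A
#'   single control antibody's counts; see [isotype_correlation()] for
#'   choosing among several.
#' @param design an [adt_design()]: intercept column `mu0` plus integer-coded
#'   categorical covariates.
#' @param priors an [adtgp_priors()]. Tune the `rho_sq` bound with
#'   [tune_rhosq()] before fitting — raw counts set the distance scale.
#' @param chains number of independent chains (default 4).
#' @param iter_warmup warmup iterations per chain (default 3000).
#' @param iter_sampling kept iterations per chain (default 1000).
#' @param seed integer seed; chain `c` uses `seed + c - 1`, and the
#'   conditional predictive draws use `seed + 1000`. Identical inputs and
#'   seed give bit-identical results.
#' @return An object of class `adtgp_fit` with elements
#'   \describe{
#'     \item{draws}{named list of posterior draws: `mu0`, `phi`, `eta_sq`,
#'       `rho_sq` as iteration x chain matrices; `betas` and `gamma` as
#'       iteration x chain x dimension arrays.}
#'     \item{cond_samples}{matrix (all kept draws x combinations) of
#'       posterior-predictive counts at equal isotype noise (offset 0), one
#'       column per covariate-level combination.}
#'     \item{combination_labels}{data frame of level tuples per column.}
#'     \item{diagnostics}{[diagnostics_summary()] table.}
#'     \item{sampler_config}{chains, iterations, seed, priors.}
#'   }
#' @examples
#' \donttest{
#' sim <- run_simulation(simulation_config(seed = 1))
#' pri <- tune_rhosq(sim$igg)
#' fit <- adtgp(sim$protein, sim$igg,
#'              adt_design(data.frame(mu0 = 1, T = sim$treatment)),
#'              priors = pri, chains = 2, iter_warmup = 500,
#'              iter_sampling = 500, seed = 1)
#' summary(log2fc_posterior(fit, "T=1", "T=2"))
#' }
#' @export
adtgp <- function(protein, igg, design, priors = adtgp_priors(), chains = 4,
                  iter_warmup = 3000, iter_sampling = 1000, seed = 1) {
  if (!is_count_vector(protein) || !is_count_vector(igg)) {
    adtgp_error("protein and igg must be nonnegative integer vectors",
                "adtgp_error_domain")
  }
  design <- if (inherits(design, "adt_design")) design else adt_design(design)
  n <- nrow(design)
  if (length(protein) != n || length(igg) != n) {
    adtgp_error(sprintf(
      "non-conformable inputs: %d protein counts, %d isotype counts, %d design rows",
      length(protein), length(igg), n), "adtgp_error_dimension")
  }
  if (n < 2) adtgp_error("need at least 2 cells", "adtgp_error_dimension")
  if (chains < 1 || iter_warmup < 1 || iter_sampling < 1) {
    adtgp_error("chains and iteration counts must be >= 1",
                "adtgp_error_invalid_parameter")
  }
  stopifnot(inherits(priors, "adtgp_priors"))
  seed <- as.integer(seed)
  rho_fixed <- priors$rhosq_hi <= priors$rhosq_lo

  # free coefficients: levels 2..L of every non-intercept column
  lv <- design_levels(design)
  lev_names <- character(0)
  cols <- list()
  for (j in names(lv)) {
    if (lv[[j]] > 1) {
      for (l in 2:lv[[j]]) {
        lev_names <- c(lev_names, sprintf("beta_%s[%d]", j, l))
        cols[[length(cols) + 1]] <- as.numeric(design[[j]] == l)
      }
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)

  res <- lapply(seq_len(chains), function(c)
    run_chain(protein, igg, X, lev_names, priors, iter_warmup, iter_sampling,
              seed + c - 1L, rho_fixed))

  bind2 <- function(name) sapply(res, `[[`, name)   # iter x chains
  nb <- length(lev_names)
  betas <- array(NA_real_, c(iter_sampling, chains, nb),
                 dimnames = list(NULL, NULL, lev_names))
  for (c in seq_len(chains)) betas[, c, ] <- res[[c]]$beta
  gamma <- array(NA_real_, c(iter_sampling, chains, n))
  for (c in seq_len(chains)) gamma[, c, ] <- res[[c]]$gamma

  fit <- structure(list(
    draws = list(mu0 = bind2("mu0"), phi = bind2("phi"),
                 eta_sq = bind2("eta_sq"), rho_sq = bind2("rho_sq"),
                 betas = betas, gamma = gamma),
    design = design,
    combination_labels = design_combinations(design),
    sampler_config = list(chains = chains, iter_warmup = iter_warmup,
                          iter_sampling = iter_sampling, seed = seed,
                          priors = priors)),
    class = "adtgp_fit")
  fit$cond_samples <- conditional_posterior(fit)
  fit$diagnostics <- diagnostics_summary(fit)
  fit
}

#' @export
print.adtgp_fit <- function(x, ...) {
  sc <- x$sampler_config
  cat(sprintf("GP count-model fit: %d chains x %d draws (warmup %d)\n",
              sc$chains, sc$iter_sampling, sc$iter_warmup))
  cat(sprintf("posterior means: mu0 = %.3f, phi = %.2f, eta_sq = %.3f, rho_sq = %.4g\n",
              mean(x$draws$mu0), mean(x$draws$phi), mean(x$draws$eta_sq),
              mean(x$draws$rho_sq)))
  if (dim(x$draws$betas)[3] > 0) {
    bm <- apply(x$draws$betas, 3, mean)
    cat("coefficients:", paste(sprintf("%s = %.3f", names(bm), bm), collapse = ", "),
        "\n")
  }
  cat(sprintf("conditional samples: %d draws x %d combination%s\n",
              nrow(x$cond_samples), ncol(x$cond_samples),
              if (ncol(x$cond_samples) == 1) "" else "s"))
  invisible(x)
}

#' Extract posterior draws of one parameter
#'
#' @param fit an [adtgp()] fit.
#' @param parameter one of `"mu0"`, `"phi"`, `"eta_sq"`, `"rho_sq"`, a
#'   coefficient name such as `"beta_T[2]"`, or `"gamma"`.
#' @return matrix iterations x chains (array for `"gamma"`).
#' @export
posterior_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "adtgp_fit"))
  if (parameter %in% names(fit$draws)) return(fit$draws[[parameter]])
  bn <- dimnames(fit$draws$betas)[[3]]
  if (parameter %in% bn) return(fit$draws$betas[, , match(parameter, bn)])
  adtgp_error(sprintf("unknown parameter '%s'", parameter),
              "adtgp_error_invalid_parameter")
}

#' Conditional predictive counts at equal isotype noise
#'
#' For every kept posterior draw and every combination of covariate levels,
#' draws one negative-binomial count with mean `exp(mu0 + sum(beta))` and the
#' draw's dispersion `phi`, holding the Gaussian-process offset at its prior
#' mean 0 — i.e. all cells share the same (reference) isotype control noise.
#' These are predictive counts, matching how conditional expression
#' distributions are plotted, not posterior means.
#'
#' @param fit an [adtgp()] fit.
#' @param design optional design; must match the fit's design (covariate
#'   names and level counts).
#' @param type `"predictive"` (default): one NB count draw per posterior
#'   draw and combination. `"mean"`: the conditional mean
#'   `exp(mu0 + sum(beta))` itself, i.e. the posterior of the expression
#'   level rather than of a new count — the tighter quantity to use when
#'   comparing point-estimate accuracy against a baseline.
#' @param seed seed for the predictive draws; defaults to the fit seed +
#'   1000. Ignored for `type = "mean"` (deterministic in the draws).
#' @return matrix with `iter_sampling * chains` rows and one column per
#'   covariate-level combination, labeled e.g. `"T=1"`; lexicographic order
#'   with earlier design columns most significant. Attribute `type` records
#'   which quantity the columns hold.
#' @export
conditional_posterior <- function(fit, design = NULL,
                                  type = c("predictive", "mean"),
                                  seed = fit$sampler_config$seed + 1000L) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "adtgp_fit"))
  if (!is.null(design)) {
    design <- if (inherits(design, "adt_design")) design else adt_design(design)
    if (!identical(design_levels(design), design_levels(fit$design))) {
      adtgp_error("design does not match the fitted design",
                  "adtgp_error_design_mismatch")
    }
  }
  combos <- fit$combination_labels
  labels <- attr(combos, "labels")
  mu0 <- as.vector(fit$draws$mu0)
  phi <- as.vector(fit$draws$phi)
  nd <- length(mu0)
  betas <- fit$draws$betas
  bn <- dimnames(betas)[[3]]
  out <- matrix(NA_real_, nd, nrow(combos), dimnames = list(NULL, labels))
  with_seed(seed, {
    for (ci in seq_len(nrow(combos))) {
      lp <- mu0
      for (j in names(combos)) {
        l <- combos[ci, j]
        if (l > 1) {
          k <- match(sprintf("beta_%s[%d]", j, l), bn)
          lp <- lp + as.vector(betas[, , k])
        }
      }
      out[, ci] <- if (type == "mean") exp(lp)
                   else stats::rnbinom(nd, size = phi, mu = exp(lp))
    }
  })
  attr(out, "type") <- type
  out
}

#' Prior predictive counts per covariate combination
#'
#' Same shape contract as [conditional_posterior()], but all parameters are
#' drawn from the priors: use it to audit the count ranges and the kernel
#' decay implied by a prior configuration before fitting (the draws of
#' `eta_sq` and `rho_sq` are attached as attribute `"kernel_draws"`, from
#' which covariance-vs-distance curves can be plotted for the observed
#' isotype counts).
#'
#' @param priors an [adtgp_priors()].
#' @param design an [adt_design()].
#' @param igg isotype counts; used only for the attached kernel audit.
#' @param n_draws number of prior draws (default 1000).
#' @param seed seed.
#' @return integer matrix `n_draws` x combinations with attribute
#'   `kernel_draws` (data frame of `eta_sq`, `rho_sq` draws).
#' @examples
#' d <- adt_design(data.frame(mu0 = 1, T = rep(1:2, 5)))
#' pp <- prior_predictive(adtgp_priors(), d, rep(20L, 10), n_draws = 100, seed = 1)
#' dim(pp)
#' @export
prior_predictive <- function(priors, design, igg = NULL, n_draws = 1000, seed = 1) {
  stopifnot(inherits(priors, "adtgp_priors"))
  design <- if (inherits(design, "adt_design")) design else adt_design(design)
  if (n_draws < 1) adtgp_error("n_draws must be >= 1", "adtgp_error_invalid_parameter")
  combos <- design_combinations(design)
  labels <- attr(combos, "labels")
  with_seed(seed, {
    mu0 <- stats::rgamma(n_draws, priors$mu0_shape, priors$mu0_rate)
    phi <- stats::rgamma(n_draws, priors$phi_shape, priors$phi_rate)
    # truncated normal via inverse cdf
    p0 <- stats::pnorm(0, priors$etasq_loc, priors$etasq_scale)
    eta2 <- stats::qnorm(p0 + stats::runif(n_draws) * (1 - p0),
                         priors$etasq_loc, priors$etasq_scale)
    rho2 <- stats::runif(n_draws, priors$rhosq_lo, priors$rhosq_hi)
    lv <- design_levels(design)
    bdraw <- list()
    for (j in names(lv)) {
      bj <- matrix(0, n_draws, lv[[j]])
      if (lv[[j]] > 1) {
        bj[, -1] <- stats::rnorm(n_draws * (lv[[j]] - 1), priors$beta_loc,
                                 priors$beta_scale)
      }
      bdraw[[j]] <- bj
    }
    out <- matrix(NA_integer_, n_draws, nrow(combos), dimnames = list(NULL, labels))
    for (ci in seq_len(nrow(combos))) {
      lp <- mu0
      for (j in names(combos)) lp <- lp + bdraw[[j]][, combos[ci, j]]
      out[, ci] <- stats::rnbinom(n_draws, size = phi, mu = exp(lp))
    }
    attr(out, "kernel_draws") <- data.frame(eta_sq = eta2, rho_sq = rho2)
    out
  })
}
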
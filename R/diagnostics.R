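# Convergence diagnostics: split-chain rank-normalized Rhat and bulk ESS
# (Vehtari, Gelman, Simpson, Carpenter & Buerkner 2021 style).

# split each chain in half; m: iterations x chains -> iterations/2 x 2*chains
split_chains <- function(m) {
  n <- nrow(m)
  half <- n %/% 2
  cbind(m[seq_len(half), , drop = FALSE],
        m[(n - half + 1):n, , drop = FALSE])
}

# rank-normalize jointly over all chains (fractional offset 3/8)
rank_normalize <- function(m) {
  r <- rank(m, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

basic_rhat <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  if (W == 0) return(NA_real_)
  sqrt((n - 1) / n + B / (W * n))
}

#' Split-chain rank-normalized Rhat
#'
#' Potential-scale-reduction statistic computed on rank-normalized draws
#' after splitting every chain in half; values near 1 indicate that the
#' chains have mixed. Requires at least two chains (after splitting, two
#' halves of a single chain are used, which still detects trends).
#'
#' @param draws matrix of posterior draws, iterations x chains.
#' @return single Rhat value (NA for constant draws).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 4) return(NA_real_)
  sm <- split_chains(draws)
  if (all(sm == sm[1])) return(NA_real_)
  basic_rhat(rank_normalize(sm))
}

# per-chain autocovariance via FFT
chain_autocov <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  np <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, np - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / np
  ac / ac[1] * sum(x^2) / n
}

#' Bulk effective sample size
#'
#' Effective sample size of rank-normalized split chains, combining
#' per-chain autocovariances with Geyer's initial monotone positive sequence.
#'
#' @param draws matrix of posterior draws, iterations x chains.
#' @return effective sample size (NA for constant draws).
#' @export
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 4) return(NA_real_)
  sm <- split_chains(draws)
  if (all(sm == sm[1])) return(NA_real_)
  z <- rank_normalize(sm)
  n <- nrow(z); m <- ncol(z)
  acov <- apply(z, 2, chain_autocov)
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  mean_var <- W * (n - 1) / n
  var_plus <- mean_var + (if (m > 1) stats::var(colMeans(z)) else 0)
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  max_t <- 1
  t <- 1
  rho_sum <- rho[1] + (if (n > 2) rho[2] else 0)
  pair_prev <- rho_sum
  total <- rho_sum
  t <- 3
  while (t + 1 <= n) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, pair_prev)
    total <- total + pair
    pair_prev <- pair
    t <- t + 2
  }
  tau <- max(2 * total - 1, 1 / log10(n * m + 10))
  min(n * m / tau, n * m * log10(n * m))
}

#' Convergence diagnostics table
#'
#' Per-parameter split-chain rank-normalized Rhat and bulk effective sample
#' size for a fitted model; the fit is flagged converged when every Rhat is
#' at most `rhat_max` and every ESS is at least `ess_min`. With a single
#' chain, Rhat is reported as NA (not 1).
#'
#' @param fit an [adtgp()] fit.
#' @param rhat_max convergence threshold on Rhat (default 1.01).
#' @param ess_min convergence threshold on ESS (default 100).
#' @return data frame with columns `parameter`, `rhat`, `ess`; attribute
#'   `converged` (logical) and a `converged` column message via print.
#' @export
diagnostics_summary <- function(fit, rhat_max = 1.01, ess_min = 100) {
  stopifnot(inherits(fit, "adtgp_fit"))
  single <- ncol(fit$draws$mu0) < 2
  scalar <- c("mu0", "phi", "eta_sq", "rho_sq")
  rows <- lapply(scalar, function(p) {
    m <- fit$draws[[p]]
    data.frame(parameter = p,
               rhat = if (single) NA_real_ else split_rhat(m),
               ess = ess_bulk(m))
  })
  b <- fit$draws$betas
  if (!is.null(b) && length(dim(b)) == 3 && dim(b)[3] > 0) {
    for (k in seq_len(dim(b)[3])) {
      m <- b[, , k]
      rows[[length(rows) + 1]] <- data.frame(
        parameter = dimnames(b)[[3]][k],
        rhat = if (single) NA_real_ else split_rhat(m),
        ess = ess_bulk(m))
    }
  }
  out <- do.call(rbind, rows)
  conv <- !single && all(out$rhat <= rhat_max, na.rm = FALSE) &&
    all(out$ess >= ess_min)
  attr(out, "converged") <- isTRUE(conv)
  class(out) <- c("adtgp_diagnostics", "data.frame")
  out
}

#' @export
print.adtgp_diagnostics <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(if (isTRUE(attr(x, "converged"))) "fit flagged: converged\n"
      else "fit flagged: NOT converged\n")
  invisible(x)
}
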
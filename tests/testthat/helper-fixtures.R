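# shared fixtures, built in code

with_restored_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

toy_panel <- function(n = 20, seed = 7) {
  with_restored_rng(seed, {
    m <- cbind(CD11b = rnbinom(n, mu = 100, size = 2),
               CD71 = rnbinom(n, mu = 40, size = 2),
               IgG1 = rnbinom(n, mu = 20, size = 5),
               IgG2a = rnbinom(n, mu = 18, size = 5))
    adt_counts(m)
  })
}

two_group_design <- function(n_per = 5) {
  adt_design(data.frame(mu0 = 1, T = rep(1:2, each = n_per)))
}

# small fitted model shared across tests (cheap settings; cached per session)
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- run_simulation(simulation_config(seed = 3, pool_size = 2000,
                                              n_cells = 30))
      pri <- tune_rhosq(sim$igg)
      d <- adt_design(data.frame(mu0 = 1, T = sim$treatment))
      cache <<- list(sim = sim,
                     fit = adtgp(sim$protein, sim$igg, d, priors = pri,
                                 chains = 2, iter_warmup = 300,
                                 iter_sampling = 200, seed = 11))
    }
    cache
  }
})
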
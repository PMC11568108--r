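test_that("log2 fold change posterior handles null, scaling and antisymmetry", {
  m <- cbind("T=1" = rep(10L, 200), "T=2" = rep(10L, 200))
  e <- log2fc_posterior(m, "T=1", "T=2")
  expect_true(all(e$log2fc_draws == 0))
  expect_identical(e$pseudo_p, 1)
  # exact doubling: draws ~ 1 up to the half-count guard
  m2 <- cbind("T=1" = 2L * (1000:1199), "T=2" = 1000:1199)
  e2 <- log2fc_posterior(m2, "T=1", "T=2")
  expect_equal(mean(e2$log2fc_draws), 1, tolerance = 1e-3)
  # antisymmetry
  with_restored_rng(2, {
    m3 <- cbind("T=1" = rnbinom(500, mu = 50, size = 3),
                "T=2" = rnbinom(500, mu = 30, size = 3))
  })
  a <- log2fc_posterior(m3, "T=1", "T=2")
  b <- log2fc_posterior(m3, "T=2", "T=1")
  expect_equal(a$log2fc_draws, -b$log2fc_draws)
  expect_error(log2fc_posterior(m3, "T=1", "T=9"),
               class = "adtgp_error_invalid_parameter")
  # median lies inside any central interval of level >= 0.5
  for (lv in c(0.5, 0.8, 0.95)) {
    ci <- central_interval(a, lv)
    expect_gte(a$posterior_median, ci[1])
    expect_lte(a$posterior_median, ci[2])
  }
})

test_that("pseudo p-value: floor, symmetry, direct count, scale invariance", {
  expect_identical(pseudo_p(rep(1, 1000)), 1 / 1000)
  expect_identical(pseudo_p(rep(c(-1, 1), 500)), 1)
  expect_identical(pseudo_p(c(rep(1, 950), rep(-1, 50))), 0.10)
  with_restored_rng(3, {
    d <- rnorm(1000, 0.5)
    expect_identical(pseudo_p(d), pseudo_p(d * 37.5))
  })
  expect_error(pseudo_p(rnorm(50)), class = "adtgp_error_invalid_parameter")
})

test_that("CLR transform centers every cell and matches hand computation", {
  p <- toy_panel()
  m <- clr_normalize(p)
  expect_lt(max(abs(rowSums(m))), 1e-12)
  # [3, 0] with pseudocount 1: log(4)/2 split
  one <- clr_normalize(matrix(c(3L, 0L), 1, 2,
                              dimnames = list("c", c("A", "B"))))
  expect_equal(unname(one[1, ]), c(log(4) / 2, -log(4) / 2), tolerance = 1e-12)
  # 4-cell toy, brute-force arithmetic
  toy <- matrix(c(10L, 2L, 8L, 4L, 1L, 9L, 3L, 7L), 4, 2,
                dimnames = list(paste0("c", 1:4), c("A", "B")))
  want <- t(apply(toy, 1, function(r) log(r + 1) - mean(log(r + 1))))
  expect_equal(unname(clr_normalize(toy)), unname(want), tolerance = 1e-14)
  expect_warning(clr_normalize(matrix(1L, 2, 1)), "single-antibody")
})

test_that("CLR is scale-invariant per cell only in the large-count limit", {
  with_restored_rng(9, {
    big <- matrix(rnbinom(60, mu = 2000, size = 20) + 100L, 20, 3,
                  dimnames = list(NULL, c("A", "B", "IgG1")))
  })
  m1 <- clr_normalize(big)
  m2 <- clr_normalize(big * 3L)
  expect_lt(max(abs(m1 - m2)), 0.01)
})

test_that("CLR effect reduces to hand-computed means and flags tiny groups", {
  toy <- adt_counts(matrix(c(10L, 2L, 8L, 4L, 1L, 9L, 3L, 7L), 4, 2,
                           dimnames = list(paste0("c", 1:4), c("A", "IgG1"))))
  groups <- c(1, 1, 2, 2)
  eff <- clr_effect(toy, "A", groups)
  v <- clr_normalize(toy)[, "A"]
  expect_equal(eff$estimate, mean(v[1:2]) - mean(v[3:4]), tolerance = 1e-14)
  # identical groups: zero estimate, p = 1
  dup <- adt_counts(matrix(rep(c(5L, 9L, 2L, 4L), 2), 4, 2, byrow = FALSE,
                           dimnames = list(paste0("c", 1:4), c("A", "IgG1"))))
  same <- clr_effect(dup, "A", c(1, 2, 1, 2))
  expect_equal(same$estimate, 0)
  expect_equal(same$p_value, 1)
  expect_error(clr_effect(toy, "A", c(1, 2, 2, 2)),
               class = "adtgp_error_invalid_parameter")
})

test_that("RMSE comparison follows its definition", {
  e <- structure(list(log2fc_draws = c(2, 2, 2, 2)), class = "effect_summary")
  expect_warning(r0 <- rmse_comparison(e, clr_estimate = 1, truth = 2))
  expect_identical(r0$rmse_adtgp, 0)
  expect_identical(r0$ratio, Inf)
  e2 <- structure(list(log2fc_draws = c(1, 3, 1, 3)), class = "effect_summary")
  r <- rmse_comparison(e2, clr_estimate = -0.5, truth = 2)
  expect_identical(r$rmse_adtgp, 1)
  expect_identical(r$rmse_clr, 2.5)
  expect_identical(r$ratio, 2.5)
})

test_that("isotype correlations: duplicates, independence, comonotone pairs", {
  dup <- toy_panel()
  dup2 <- adt_counts(cbind(unclass(dup), IgG2b = dup[, "IgG1"]))
  ic <- isotype_correlation(dup2)
  r <- ic[ic$antibody_a == "IgG1" & ic$antibody_b == "IgG2b", ]
  expect_equal(r$pearson, 1, tolerance = 1e-12)
  with_restored_rng(11, {
    ind <- adt_counts(cbind(IgG1 = rnbinom(1e4, mu = 20, size = 5),
                            IgG2a = rnbinom(1e4, mu = 20, size = 5)))
  })
  ri <- isotype_correlation(ind)
  expect_lt(abs(ri$pearson), 0.05)
  qc <- quantile_couple(20, 5, 18, 4, n = 1e4, seed = 12)
  com <- adt_counts(cbind(IgG1 = qc[, 1], IgG2a = qc[, 2]))
  expect_gt(isotype_correlation(com)$spearman, 0.95)
  # constant column: correlation reported missing, not an error
  cst <- adt_counts(cbind(IgG1 = rep(4L, 10), IgG2a = 1:10))
  expect_true(is.na(isotype_correlation(cst)$pearson))
  expect_error(isotype_correlation(toy_panel()[, 1:2]),
               class = "adtgp_error")
})

test_that("differential sweep analyzes every antibody and ranks a true shift", {
  with_restored_rng(13, {
    n <- 30
    qc1 <- quantile_couple(120, 3, 20, 5, n, seed = 31)   # shifted antibody
    qc0 <- quantile_couple(60, 3, 20, 5, n, seed = 32)
    igg <- qc1[, "b"]
    shifted <- as.integer(round(qc1[, "a"] * rep(c(2, 1), each = n / 2)))
    flat <- qc0[, "a"]
    panel <- adt_counts(cbind(Hit = shifted, Flat = flat, IgG1 = igg))
  })
  d <- adt_design(data.frame(mu0 = 1, T = rep(1:2, each = 15)))
  de <- differential_sweep(panel, "IgG1", d, chains = 1, iter_warmup = 200,
                           iter_sampling = 150, seed = 5)
  expect_s3_class(de, "adtgp_de")
  # (n_antibodies - 1 control) x 2 methods rows
  expect_identical(nrow(de), 4L)
  expect_setequal(unique(de$antibody), c("Hit", "Flat"))
  expect_true(all(de$fit_status == "ok"))
  for (m in c("ADTGP", "CLR")) {
    sub <- de[de$method == m, ]
    expect_identical(sub$antibody[which.max(abs(sub$estimate))], "Hit")
  }
  expect_true(all(!de$is_isotype))
  expect_true(all(de$bh_fdr >= de$significance - 1e-12))
})
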
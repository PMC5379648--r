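## A quick simulated univariate dataset with known h2 over a given panel.
sim_uni <- function(panel, h2, n_causal = 200, seed = 1) {
  set.seed(seed)
  causal <- sample(panel$snps$snp_id, n_causal)
  Z <- scale(panel$dosages[, causal])
  b <- rnorm(n_causal, 0, sqrt(h2 / n_causal))
  g <- as.vector(Z %*% b)
  y <- g + rnorm(nrow(Z), 0, sqrt(max(1 - h2, 1e-12)))
  setNames(y, panel$sample_ids)
}

test_that("univariate REML matches a dense grid-search oracle (n = 60)", {
  p <- small_panel(60, 150, seed = 101)
  g <- suppressWarnings(compute_grm(p))
  y <- sim_uni(p, 0.5, 80, seed = 102)
  fit <- suppressWarnings(reml_univariate(y, g))
  ## oracle: dense restricted likelihood over a 51 x 51 grid
  A <- g$values
  X <- matrix(1, 60, 1)
  grid <- seq(0.01, 1.5, length.out = 51)
  best <- -Inf
  for (sg in grid) for (se in grid) {
    ll <- reml_ll_oracle(y, X, sg * A + se * diag(60))
    if (ll > best) best <- ll
  }
  expect_gte(fit$loglik_full, best - 1e-3)
  ## the engine's optimum beats or ties every grid point
  expect_true(fit$converged)
  ## gradient at an interior solution is ~0 (checked via tiny perturbations)
  eps <- 1e-5
  for (d in list(c(eps, 0), c(0, eps))) {
    ll_p <- reml_ll_oracle(y, X, (fit$sigma2_g + d[1]) * A +
                                 (fit$sigma2_e + d[2]) * diag(60))
    expect_lte(ll_p, fit$loglik_full + 1e-7)
  }
})

test_that("univariate REML recovers simulated heritability and rejects nulls", {
  p <- simulate_genotypes(800, 1000, 0.05, 0.5, seed = 111)
  g <- compute_grm(p)
  y <- sim_uni(p, 0.4, 300, seed = 112)
  fit <- reml_univariate(y, g)
  expect_true(fit$converged)
  expect_lt(abs(fit$var_g - 0.4), 2 * fit$se_var_g)
  expect_lt(fit$lrt_p, 0.05)
  ## permuting y against the GRM destroys h2
  set.seed(113)
  yp <- setNames(sample(y), names(y))
  fit0 <- reml_univariate(yp, g)
  expect_lt(fit0$var_g, 0.15)
  expect_gt(fit0$lrt_p, 0.01)
  ## loglik ordering invariant
  expect_gte(fit$loglik_full, fit$loglik_null - 1e-6)
})

test_that("dense and eigen-rotated REML agree on the same data", {
  p <- small_panel(80, 200, seed = 121)
  g <- suppressWarnings(compute_grm(p))
  y <- sim_uni(p, 0.3, 100, seed = 122)
  fit <- suppressWarnings(reml_univariate(y, g))
  be <- gcovpipe:::make_dense_backend(unname(y), matrix(1, 80, 1),
                                      list(g$values, diag(80)))
  fit_d <- gcovpipe:::reml_ai_fit(be, c(0.5, 0.5), is_var = c(TRUE, TRUE),
                                  scale = 1)
  expect_equal(fit_d$loglik, fit$loglik_full, tolerance = 1e-6)
  expect_equal(unname(fit_d$theta),
               c(fit$sigma2_g, fit$sigma2_e), tolerance = 1e-3)
})

test_that("bivariate REML recovers shared architecture on complete overlap", {
  p <- simulate_genotypes(700, 900, 0.05, 0.5, seed = 131)
  g <- compute_grm(p)
  eig <- eigen(g$values, symmetric = TRUE)
  set.seed(132)
  causal <- sample(p$snps$snp_id, 300)
  Z <- scale(p$dosages[, causal])
  b <- rnorm(300, 0, sqrt(0.4 / 300))
  gval <- as.vector(Z %*% b)
  ## r_g = 1: same genetic values, independent residuals
  y1 <- setNames(gval + rnorm(700, 0, sqrt(0.6)), p$sample_ids)
  y2 <- setNames(gval + rnorm(700, 0, sqrt(0.6)), p$sample_ids)
  fit <- reml_bivariate(y1, y2, g, eig = eig)
  expect_true(fit$converged)
  expect_lt(abs(fit$r_g - 1) , 2 * fit$se_r_g + 1e-6)
  expect_lt(fit$lrt_p_rg0, 0.05)
  ## invariant: cov_g = r_g sqrt(h2_1 h2_2) exactly
  expect_equal(fit$cov_g, fit$r_g * sqrt(fit$h2_1 * fit$h2_2),
               tolerance = 1e-8)

  ## disjoint causal sets: r_g near 0
  b2 <- rnorm(300, 0, sqrt(0.4 / 300))
  Z2 <- scale(p$dosages[, sample(setdiff(p$snps$snp_id, causal), 300)])
  y3 <- setNames(as.vector(Z2 %*% b2) + rnorm(700, 0, sqrt(0.6)),
                 p$sample_ids)
  fit0 <- reml_bivariate(y1, y3, g, eig = eig)
  if (is.finite(fit0$se_r_g) && !is.na(fit0$r_g))
    expect_lt(abs(fit0$r_g), 2 * fit0$se_r_g + 0.05)
  expect_gt(fit0$lrt_p_rg0, 0.01)
})

test_that("identical traits give r_g and r_e at the upper bound", {
  p <- small_panel(150, 300, seed = 141)
  g <- suppressWarnings(compute_grm(p))
  y <- sim_uni(p, 0.5, 100, seed = 142)
  fit <- suppressMessages(reml_bivariate(y, y, g))
  expect_gt(fit$r_g, 0.999)
  expect_gt(fit$r_e, 0.999)
})

test_that("partial-overlap bivariate fits use all individuals", {
  p <- small_panel(150, 300, seed = 151)
  g <- suppressWarnings(compute_grm(p))
  y <- sim_uni(p, 0.5, 120, seed = 152)
  y2 <- y + rnorm(150, 0, 0.3)
  ids <- p$sample_ids
  fit <- suppressWarnings(
    reml_bivariate(y[ids[1:120]], y2[ids[31:150]], g))
  expect_equal(fit$n_overlap, 90)
  expect_true(is.finite(fit$loglik_full))
  ## strongly shared traits show high r_g even at partial overlap
  expect_gt(fit$cov_g, 0)
})

test_that("partitioned REML recovers an enriched set share", {
  p <- simulate_genotypes(600, 800, 0.05, 0.5, seed = 161)
  set.seed(162)
  set_ids <- sample(p$snps$snp_id, 200)
  noset_ids <- setdiff(p$snps$snp_id, set_ids)
  ## 30% of a total h2 = 0.5 from set SNPs
  cs <- sample(set_ids, 100); cn <- sample(noset_ids, 200)
  Zs <- scale(p$dosages[, cs]); Zn <- scale(p$dosages[, cn])
  gs <- as.vector(Zs %*% rnorm(100, 0, sqrt(0.15 / 100)))
  gn <- as.vector(Zn %*% rnorm(200, 0, sqrt(0.35 / 200)))
  y <- setNames(gs + gn + rnorm(600, 0, sqrt(0.5)), p$sample_ids)
  g_set <- compute_grm(p, set_ids)
  g_noset <- compute_grm(p, noset_ids)
  fit <- reml_partitioned(y, g_set, g_noset)
  expect_true(fit$converged)
  expect_lt(abs(fit$var_set - 0.15), 2 * fit$se_var_set)
  expect_lte(fit$var_set + fit$var_noset, 1 + 1e-6)
  expect_gte(fit$loglik_full, fit$loglik_null - 1e-6)
  ## degenerate empty component is rejected
  expect_error(reml_partitioned(y, g_set,
                                structure(list(sample_ids = p$sample_ids,
                                               values = g_noset$values,
                                               pair_snp_counts = g_noset$pair_snp_counts,
                                               n_snps = 0L), class = "grm")),
               "empty component")
})

test_that("boundary LRT rejection is calibrated under the null", {
  ## 200 small replicates with h2 = 0: rejection rate at alpha = .05
  ## should land in the conservative band of the 50:50 mixture
  set.seed(171)
  rej <- logical(200)
  for (r in 1:200) {
    p <- simulate_genotypes(120, 160, 0.1, 0.5, seed = 1000 + r)
    g <- suppressWarnings(compute_grm(p))
    y <- setNames(rnorm(120), p$sample_ids)
    fit <- suppressWarnings(reml_univariate(y, g, max_iter = 60))
    rej[r] <- fit$lrt_p < 0.05
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})
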
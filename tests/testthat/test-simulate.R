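test_that("simulated genotype panels respect the generating frequencies", {
  p <- simulate_genotypes(1000, 200, 0.05, 0.5, seed = 1)
  obs <- colMeans(p$dosages) / 2
  gen <- p$snps$allele_freq
  bound <- 4 * sqrt(gen * (1 - gen) / (2 * 1000))
  expect_gte(mean(abs(obs - gen) < bound), 0.95)
  ## layout invariants
  expect_true(all(p$snps$allele_freq >= 0.01 & p$snps$allele_freq <= 0.99))
  for (ch in unique(p$snps$chromosome)) {
    pos <- p$snps$position[p$snps$chromosome == ch]
    expect_true(all(diff(pos) > 0))
  }
  expect_identical(dim(p$dosages), c(1000L, 200L))
})

test_that("degenerate panels and seeded determinism behave", {
  tiny <- simulate_genotypes(2, 1, 0.499, 0.5, seed = 5)
  expect_true(all(tiny$dosages %in% 0:2))
  a <- simulate_genotypes(50, 30, 0.05, 0.5, seed = 7)
  b <- simulate_genotypes(50, 30, 0.05, 0.5, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_genotypes(10, 10, 0.5, 0.05), "MAF bounds")
  expect_error(simulate_genotypes(10, 10, 0.001, 0.5), "MAF bounds")
})

test_that("simulated annotations are non-overlapping inclusive intervals", {
  p <- small_panel()
  ann <- simulate_annotation(p, 50, mean_length = 2e4, seed = 3)
  expect_equal(nrow(ann), 50)
  expect_true(all(ann$start <= ann$end))
  expect_true(all(ann$chromosome %in% 1:22))
  for (ch in unique(ann$chromosome)) {
    g <- ann[ann$chromosome == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  ## zero-length mean gives point genes (start == end allowed)
  pt <- simulate_annotation(p, 5, mean_length = 1e-9, seed = 2)
  expect_true(all(pt$start == pt$end))
  ## different seeds: same count, different layout
  ann2 <- simulate_annotation(p, 50, mean_length = 2e4, seed = 4)
  expect_equal(nrow(ann2), 50)
  expect_false(identical(ann$start, ann2$start))
})

test_that("longitudinal traits carry the requested architecture", {
  p <- simulate_genotypes(800, 600, 0.05, 0.5, seed = 11)
  spec <- trait_sim_spec(n_causal = 300, seed = 9)
  pheno <- simulate_longitudinal_traits(p, spec)
  labs <- attr(pheno, "labels")
  expect_equal(length(labs), 9)
  expect_equal(nrow(pheno), 800 * 9)
  ## raw scores within the declared ranges
  expect_true(all(pheno$score[pheno$trait == "adhd"] %in% 0:10))
  expect_true(all(pheno$score[pheno$trait == "scdc"] %in% 0:24))
  ## quantile map is monotone in the latent value within each measure
  one <- pheno[pheno$trait == "adhd" & pheno$age_band == 7, ]
  ord <- order(one$latent)
  expect_true(all(diff(one$score[ord]) >= 0))
  ## seeded determinism
  pheno2 <- simulate_longitudinal_traits(p, spec)
  expect_identical(pheno$score, pheno2$score)
})

test_that("per-SNP effect vectors reproduce the genetic correlation matrix", {
  p <- simulate_genotypes(50, 6000, 0.05, 0.5, seed = 21)
  spec <- trait_sim_spec(n_causal = 5000, seed = 22)
  pheno <- simulate_longitudinal_traits(p, spec)
  B <- attr(pheno, "effects")
  emp <- cor(B)
  expect_lt(max(abs(emp - spec$genetic_corr)), 0.05)
  ## column scales give the h2 targets
  expect_lt(max(abs(unname(colSums(B^2)) - unname(spec$h2))), 0.05)
})

test_that("realized latent heritability converges to the targets", {
  p <- simulate_genotypes(4000, 800, 0.05, 0.5, seed = 31)
  spec <- trait_sim_spec(n_causal = 400, seed = 32)
  pheno <- simulate_longitudinal_traits(p, spec)
  B <- attr(pheno, "effects")
  causal <- attr(pheno, "causal")$snp_id
  Z <- scale(p$dosages[, causal])
  G <- Z %*% B
  for (t in seq_along(spec$labels)) {
    one <- pheno[pheno$trait == spec$trait_of[t] &
                 pheno$age_band == spec$ages[t], ]
    h2_real <- var(G[, t]) / var(one$latent)
    expect_lt(abs(h2_real - spec$h2[t]), 0.05)
  }
})

test_that("trait spec validation rejects bad correlation matrices", {
  R <- matrix(0.5, 9, 9); diag(R) <- 1
  bad <- R; bad[1, 2] <- 0.9   # asymmetric
  expect_error(trait_sim_spec(genetic_corr = bad), "symmetric")
  neg <- diag(9); neg[1, 2] <- neg[2, 1] <- 1.5  # not PSD
  expect_error(trait_sim_spec(genetic_corr = neg), "positive semi-definite")
})

test_that("disorder GWAS nulls are standard normal and seeds reproduce", {
  p <- simulate_genotypes(50, 4000, 0.05, 0.5, seed = 41)
  ss <- simulate_disorder_gwas(p, h2_liability = 0, prevalence = 0.05,
                               n_cases = 4000, n_controls = 12000,
                               causal_ids = character(0), seed = 42)
  z <- ss$effect / ss$se
  expect_lt(abs(mean(abs(z)) - sqrt(2 / pi)), 3 * sqrt(1 - 2 / pi) / sqrt(4000))
  expect_true(all(ss$p_value > 0 & ss$p_value <= 1))
  ss2 <- simulate_disorder_gwas(p, 0, 0.05, 4000, 12000, character(0),
                                seed = 42)
  expect_identical(ss$effect, ss2$effect)
  expect_error(simulate_disorder_gwas(p, 0.3, 0.05, 100, 100, "nope"),
               "absent")
})

test_that("induced trait-disorder covariance matches its target", {
  p <- simulate_genotypes(50, 3000, 0.05, 0.5, seed = 51)
  causal <- p$snps$snp_id[1:1000]
  a <- setNames(rnorm(1000, 0, sqrt(0.4 / 1000)), causal)
  covs <- replicate(40, {
    sd <- simulate_disorder_gwas(p, 0.28, 0.05, 4000, 12000, causal,
                                 seed = sample.int(1e6, 1),
                                 trait_effects = a, target_covariance = 0.1)
    b <- attr(sd, "true_effects")
    sum(a * b[causal])
  })
  expect_lt(abs(mean(covs) - 0.1), 0.02)
})
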
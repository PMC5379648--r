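## independent clumping reference: re-scans all remaining pairs each round
clump_oracle <- function(ss, panel, r2 = 0.25, window = 5e5) {
  info <- panel$snps[match(ss$snp_id, panel$snps$snp_id), ]
  X <- panel$dosages[, ss$snp_id, drop = FALSE]
  alive <- rep(TRUE, nrow(ss))
  kept <- character(0)
  while (any(alive)) {
    cand <- which(alive)
    o <- cand[order(ss$p_value[cand], info$chromosome[cand],
                    info$position[cand])][1]
    kept <- c(kept, ss$snp_id[o])
    alive[o] <- FALSE
    for (j in which(alive)) {
      if (info$chromosome[j] == info$chromosome[o] &&
          abs(info$position[j] - info$position[o]) <= window &&
          suppressWarnings(cor(X[, j], X[, o]))^2 > r2)
        alive[j] <- FALSE
    }
  }
  kept
}

make_sumstats <- function(panel, p_values, effects = NULL) {
  m <- nrow(panel$snps)
  data.frame(snp_id = panel$snps$snp_id,
             allele_effect = panel$snps$allele_alt,
             allele_other = panel$snps$allele_ref,
             effect = effects %||% rnorm(m, 0, 0.05),
             se = 0.02, p_value = p_values,
             allele_freq = panel$snps$allele_freq,
             stringsAsFactors = FALSE)
}

test_that("clumping removes LD partners and matches the exhaustive oracle", {
  ## perfect LD pair: only the more significant SNP survives
  set.seed(1)
  x <- rbinom(40, 2, 0.4)
  p <- panel_from_dosages(cbind(x, x), position = c(1000L, 2000L))
  ss <- make_sumstats(p, c(1e-8, 1e-4))
  expect_identical(clump(ss, p), "s001")

  ## mutually uncorrelated SNPs are all retained
  set.seed(2)
  X <- qr.Q(qr(matrix(rnorm(30 * 8), 30, 8)))     # orthogonal columns
  Xd <- apply(X, 2, function(v) as.integer(cut(rank(v), 3)) - 1L)
  ## build from genuinely independent draws instead
  Xd <- sapply(1:8, function(j) rbinom(500, 2, 0.3))
  p2 <- panel_from_dosages(Xd, position = as.integer(seq(1e4, 8e4, 1e4)))
  r_off <- max(abs(cor(Xd)[upper.tri(diag(8))]))
  ss2 <- make_sumstats(p2, runif(8))
  if (r_off^2 <= 0.25) expect_setequal(clump(ss2, p2), p2$snps$snp_id)

  ## 30-SNP block-LD fixture equals the re-scanning reference
  set.seed(3)
  n <- 300
  blocks <- lapply(1:6, function(b) {
    base <- rbinom(n, 2, runif(1, 0.2, 0.5))
    sapply(1:5, function(j) {
      flip <- runif(n) < 0.15
      out <- base
      out[flip] <- rbinom(sum(flip), 2, 0.35)
      out
    })
  })
  X30 <- do.call(cbind, blocks)
  p30 <- panel_from_dosages(X30,
                            chromosome = rep(1:2, each = 15),
                            position = rep(as.integer(seq(1e5, 15e5, 1e5)), 2))
  ss30 <- make_sumstats(p30, runif(30))
  expect_identical(clump(ss30, p30), clump_oracle(ss30, p30))
  ## row-order invariance
  shuf <- sample(30)
  expect_setequal(clump(ss30[shuf, ], p30), clump(ss30, p30))
  ## duplicates keep the smaller p
  dup <- rbind(ss30, transform(ss30[1, ], p_value = 1e-9))
  expect_message(kept <- clump(dup, p30), "duplicate")
  expect_true(ss30$snp_id[1] %in% kept)
})

test_that("scores are linear, allele-flip invariant and threshold-aware", {
  X <- matrix(c(0L, 1L, 2L), 3, 1)
  p <- panel_from_dosages(X, freq = 0.5)
  ss <- make_sumstats(p, 0.01, effects = 0.5)
  sc <- build_scores(p, ss, "s001", thresholds = c(0.05, 1))
  raw <- X[, 1] * 0.5
  expect_equal(sc$scores[, 1], as.vector(scale(raw)), tolerance = 1e-12)

  ## flipping the effect/other alleles flips dosage, leaving scores equal
  ss_flip <- ss
  ss_flip$allele_effect <- p$snps$allele_ref
  ss_flip$allele_other <- p$snps$allele_alt
  ss_flip$effect <- -ss$effect
  sc_flip <- build_scores(p, ss_flip, "s001", thresholds = c(0.05, 1))
  expect_equal(sc$scores, sc_flip$scores, tolerance = 1e-12)

  ## threshold semantics: P_T = 1 takes all clumped SNPs; a threshold below
  ## the smallest p yields an unusable column; counts are monotone
  pp <- small_panel(50, 20, seed = 4)
  sss <- make_sumstats(pp, seq(0.05, 1, length.out = 20))
  sc2 <- build_scores(pp, sss, pp$snps$snp_id,
                      thresholds = c(0.01, 0.5, 1))
  expect_false(sc2$usable[1])
  expect_equal(sc2$n_snps[3], 20L)
  expect_true(all(diff(sc2$n_snps) >= 0))
  expect_error(build_scores(pp, sss, pp$snps$snp_id, thresholds = 2),
               "thresholds")
  ## per-threshold standardisation
  expect_lt(abs(mean(sc2$scores[, 2])), 1e-8)
  expect_equal(var(sc2$scores[, 2]), 1, tolerance = 1e-8)
})

test_that("missing dosages contribute their frequency expectation", {
  X <- matrix(c(0L, 1L, 2L, NA_integer_), 4, 1)
  p <- panel_from_dosages(X, freq = 0.25)
  ss <- make_sumstats(p, 0.01, effects = 1)
  sc <- build_scores(p, ss, "s001", thresholds = 1)
  raw <- c(0, 1, 2, 2 * 0.25)
  expect_equal(sc$scores[, 1], as.vector(scale(raw)), tolerance = 1e-12)
})

test_that("cross-sectional association recovers perfect and null predictors", {
  pp <- small_panel(200, 30, seed = 5)
  sss <- make_sumstats(pp, runif(30, 0.002, 1))
  sc <- build_scores(pp, sss, pp$snps$snp_id, thresholds = 1)
  y <- setNames(sc$scores[, 1], pp$sample_ids)   # the score itself
  res <- suppressWarnings(assoc_cross_sectional(sc, y))  # lm: perfect fit
  expect_equal(res$beta, 1, tolerance = 1e-10)
  expect_equal(res$adj_r2, 1, tolerance = 1e-10)

  ## permuted scores: p roughly uniform across replicates
  set.seed(6)
  pv <- replicate(60, {
    yp <- setNames(sample(sc$scores[, 1]), pp$sample_ids)
    assoc_cross_sectional(sc, yp)$p
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
  expect_error(assoc_cross_sectional(sc, y[1:10]), "overlap")
})

## shared longitudinal simulation: PGS effect beta on raw scores,
## random intercepts/slopes, 4 occasions
sim_long <- function(n = 350, beta = 0.3, seed = 1, poisson = FALSE,
                     beta_age_int = 0) {
  set.seed(seed)
  ids <- sprintf("p%04d", 1:n)
  pgs <- rnorm(n)
  u0 <- rnorm(n, 0, 0.8); u1 <- rnorm(n, 0, 0.05)
  rows <- do.call(rbind, lapply(1:4, function(k) {
    age <- c(7, 10, 13, 17)[k] + rnorm(n, 0, 0.1)
    sex <- NULL
    data.frame(iid = ids, trait = "adhd", age_band = c(7, 10, 13, 17)[k],
               age = age, sex = rep(rbinom(1, 1, 0.5), n), pgs0 = pgs,
               u0 = u0, u1 = u1)
  }))
  rows$sex <- rbinom(nrow(rows), 1, 0.5)
  mu <- (beta + beta_age_int * (rows$age - 12)) * rows$pgs0 +
    0.2 * rows$sex + 0.05 * (rows$age - 12) + rows$u0 + rows$u1 * (rows$age - 12)
  rows$score <- if (poisson) rpois(nrow(rows), exp(0.8 + 0.3 * mu))
                else as.integer(pmax(0, round(4 + mu + rnorm(nrow(rows), 0, 1))))
  scores <- list(sample_ids = ids, thresholds = 0.5,
                 scores = matrix(pgs, ncol = 1,
                                 dimnames = list(NULL, "PT_0.5")),
                 n_snps = 100L, usable = TRUE)
  class(scores) <- "polygenic_scores"
  list(scores = scores, pheno = rows)
}

test_that("Gaussian longitudinal model recovers the PGS effect", {
  d <- sim_long(n = 350, beta = 0.3, seed = 11)
  res <- assoc_longitudinal_gaussian(d$scores, d$pheno, "adhd",
                                     threshold = 0.5, n_boot = 40, seed = 2)
  expect_equal(res$model_family, "gaussian")
  expect_gte(res$beta_pgs, res$ci_pgs[1])
  expect_lte(res$beta_pgs, res$ci_pgs[2])
  expect_lt(abs(res$beta_pgs - 0.3), 0.1)
  expect_true(res$ci_pgs[1] <= 0.3 && 0.3 <= res$ci_pgs[2])
  expect_gt(res$lrt_p_interaction, 0.05)   # simulated without interaction
  expect_gt(res$marginal_r2, 0)
  expect_lt(res$marginal_r2, 1)
})

test_that("zero-effect PGS yields a CI covering zero and degenerate bootstraps flag", {
  d <- sim_long(n = 250, beta = 0, seed = 13)
  res <- assoc_longitudinal_gaussian(d$scores, d$pheno, "adhd",
                                     threshold = 0.5, n_boot = 30, seed = 3)
  expect_true(res$ci_pgs[1] <= 0 && 0 <= res$ci_pgs[2])
  expect_warning(
    r1 <- assoc_longitudinal_gaussian(d$scores, d$pheno, "adhd",
                                      threshold = 0.5, n_boot = 1, seed = 4),
    "degenerate")
  expect_true(r1$degenerate_ci)
})

test_that("Poisson longitudinal model recovers log-scale effects", {
  d <- sim_long(n = 300, beta = 0.5, seed = 17, poisson = TRUE)
  ## true log-scale PGS effect is 0.3 * 0.5 = 0.15
  res <- assoc_longitudinal_poisson(d$scores, d$pheno, "adhd",
                                    threshold = 0.5, n_boot = 25, seed = 5)
  boot_se <- (res$ci_pgs[2] - res$ci_pgs[1]) / (2 * 1.96)
  expect_lt(abs(res$beta_pgs - 0.15), 2 * boot_se + 0.02)
  expect_true(is.na(res$marginal_r2))
  ## (near-)constant counts carrying no PGS signal
  d2 <- d
  d2$pheno$score <- 3L + as.integer(seq_len(nrow(d2$pheno)) %% 2L)
  res2 <- suppressWarnings(
    assoc_longitudinal_poisson(d2$scores, d2$pheno, "adhd",
                               threshold = 0.5, n_boot = 2, seed = 6))
  expect_lt(abs(res2$beta_pgs), 0.02)
})
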
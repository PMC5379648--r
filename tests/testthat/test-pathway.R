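## Small enriched cohort shared across pathway tests
make_enriched_cohort <- function(n = 300, m = 600, seed = 1,
                                 fraction = 0.7, h2 = c(0.5, 0.5)) {
  panel <- simulate_genotypes(n, m, 0.2, 0.5, seed = seed)
  ann <- simulate_annotation(panel, 60, mean_length = 3e6, seed = seed + 1)
  spec <- trait_sim_spec(
    traits = list(adhd = list(ages = 12, h2 = h2[1], max_score = 10L,
                              skew_p = 0.25),
                  scdc = list(ages = 11, h2 = h2[2], max_score = 24L,
                              skew_p = 0.12)),
    genetic_corr = matrix(c(1, 0.6, 0.6, 1), 2),
    residual_corr = matrix(c(1, 0.3, 0.3, 1), 2),
    n_causal = 200,
    enriched_set = list(gene_ids = ann$gene_id[1:15], fraction = fraction,
                        flank = 5e4),
    seed = seed + 2)
  pheno <- simulate_longitudinal_traits(panel, spec, ann)
  measures <- list(adhd_12 = transform_measure(pheno, "adhd", 12),
                   scdc_11 = transform_measure(pheno, "scdc", 11))
  list(panel = panel, ann = ann, spec = spec, measures = measures)
}

test_that("pathway scans conserve counts and are deterministic", {
  cohort <- make_enriched_cohort(n = 150, m = 300, seed = 31)
  pws <- list(enriched = cohort$ann$gene_id[1:15],
              random = cohort$ann$gene_id[31:45])
  scans <- suppressWarnings(
    pathway_scan(cohort$measures, cohort$panel, cohort$ann, pws,
                 ages = c(12, 11), trait_codes = c(1, 0)))
  expect_length(scans, 2)
  expect_equal(nrow(scans$enriched), 2)
  expect_equal(nrow(scans$random), 2)
  ## identical measure twice gives identical rows
  ms2 <- list(a = cohort$measures[[1]], b = cohort$measures[[1]])
  sc2 <- suppressWarnings(
    pathway_scan(ms2, cohort$panel, cohort$ann,
                 pws["enriched"]))$enriched
  expect_equal(sc2$var_set[1], sc2$var_set[2], tolerance = 1e-10)
  ## empty pathway skipped with warning
  tiny_ann <- rbind(cohort$ann,
                    data.frame(gene_id = "gdesert", chromosome = 22L,
                               start = 99999990L, end = 99999991L))
  expect_warning(
    out <- pathway_scan(cohort$measures, cohort$panel, tiny_ann,
                        list(desert = "gdesert")),
    "zero in-set")
  expect_length(out, 0)
})

test_that("an enriched pathway out-scores a random one across replicates", {
  wins <- logical(10)
  for (r in 1:10) {
    cohort <- make_enriched_cohort(n = 250, m = 500, seed = 100 + 7 * r)
    pws <- list(enriched = cohort$ann$gene_id[1:15],
                random = cohort$ann$gene_id[31:45])
    scans <- suppressWarnings(
      pathway_scan(cohort$measures, cohort$panel, cohort$ann, pws))
    wins[r] <- mean(scans$enriched$var_set) > mean(scans$random$var_set)
  }
  expect_gte(mean(wins), 0.9)
})

test_that("combine_correlated reduces correctly and matches the sum oracle", {
  ## single measure: Q = z^2 with z recovered from the mixture p
  scan1 <- data.frame(measure = "m1", var_set = 0.1, se_var_set = 0.05,
                      lrt_p = 0.05, z_set = qnorm(1 - 0.05))
  out1 <- combine_correlated(scan1, diag(1), n_pathways = 50)
  expect_equal(out1$Q, qnorm(0.95)^2, tolerance = 1e-12)
  ## dropping the signed root falls back to the mixture inversion, same z
  scan1b <- scan1; scan1b$z_set <- NULL
  expect_equal(combine_correlated(scan1b, diag(1))$Q, out1$Q,
               tolerance = 1e-12)
  ## identity R with equal z: Q = 2 z^2; equals an independent-sum oracle
  z <- 1.7
  scan2 <- data.frame(measure = c("m1", "m2"), var_set = 0.1,
                      se_var_set = 0.05, lrt_p = 1 - pnorm(z), z_set = z)
  out2 <- combine_correlated(scan2, diag(2))
  expect_equal(out2$Q, 2 * z^2, tolerance = 1e-10)
  expect_equal(out2$p_meta, pchisq(2 * z^2, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  ## Bonferroni attachment
  expect_equal(out2$p_adjusted, min(1, out2$p_meta * 50))
})

test_that("p_meta is uniform under a correlated null", {
  ## scan statistics drawn from their asymptotic null: z ~ N(0, R),
  ## R with off-diagonals 0.5 across 4 measures
  set.seed(41)
  m <- 4
  R <- matrix(0.5, m, m); diag(R) <- 1
  L <- chol(R)
  pm <- replicate(200, {
    z <- as.vector(t(L) %*% rnorm(m))
    scan <- data.frame(measure = paste0("m", 1:m), var_set = 0.1,
                       se_var_set = 0.05, lrt_p = 1 - pnorm(z), z_set = z)
    combine_correlated(scan, R)$p_meta
  })
  expect_gt(ks.test(pm, "punif")$p.value, 0.01)
})

test_that("matched permutation is seeded, bounded and mid-ranked for null sets", {
  cohort <- make_enriched_cohort(n = 150, m = 300, seed = 51)
  pc <- correlation_matrix(cohort$measures)
  pc$labels <- names(cohort$measures)
  dimnames(pc$values) <- list(names(cohort$measures),
                              names(cohort$measures))
  target <- cohort$ann$gene_id[31:42]   # a null (non-enriched) pathway
  perm <- suppressWarnings(
    matched_permutation(cohort$panel, cohort$ann, target, cohort$measures,
                        pc, n_perm = 19, seed = 7))
  expect_gt(perm$empirical_p, 0)
  expect_lte(perm$empirical_p, 1)
  expect_gte(perm$empirical_p, 1 / 20)
  perm2 <- suppressWarnings(
    matched_permutation(cohort$panel, cohort$ann, target, cohort$measures,
                        pc, n_perm = 19, seed = 7))
  expect_identical(perm$Q_perm, perm2$Q_perm)
  ## a null target should sit well inside its matched null distribution
  expect_gt(perm$empirical_p, 0.05)
})

test_that("meta-regression recovers an age trend and matches GLS at tau2 = 0", {
  set.seed(61)
  ages <- c(7, 10, 12, 13, 17, 8, 11, 14, 17)
  trait <- c(1, 1, 1, 1, 1, 0, 0, 0, 0)
  m <- length(ages)
  R <- 0.5 * exp(-abs(outer(ages, ages, `-`)) / 10); diag(R) <- 1
  se <- runif(m, 0.008, 0.02)
  V <- diag(se) %*% R %*% diag(se)
  truth <- 0.01 + 0.003 * ages
  reps <- 40
  betas <- ses <- numeric(reps)
  for (r in seq_len(reps)) {
    yi <- truth + as.vector(t(chol(V)) %*% rnorm(m))
    scan <- data.frame(measure = paste0("m", 1:m), age = ages,
                       trait_code = trait, var_set = yi, se_var_set = se,
                       lrt_p = 0.5, z_set = 0)
    fit <- meta_regress(scan, R, interaction = FALSE)
    betas[r] <- fit$coef$estimate[fit$coef$term == "age"]
    ses[r] <- fit$coef$se[fit$coef$term == "age"]
  }
  expect_lt(abs(mean(betas) - 0.003), 2 * sd(betas) / sqrt(reps))

  ## constant response: age and trait effects ~ 0, tau2 ~ 0
  scan_c <- data.frame(measure = paste0("m", 1:m), age = ages,
                       trait_code = trait, var_set = 0.05, se_var_set = se,
                       lrt_p = 0.5, z_set = 0)
  fit_c <- meta_regress(scan_c, R, interaction = TRUE)
  expect_lt(abs(fit_c$coef$estimate[fit_c$coef$term == "age"]), 1e-8)
  expect_lt(fit_c$tau2, 1e-8)

  ## tau2 = 0 fixed-effects fit equals the closed-form GLS solution
  yi <- truth + as.vector(t(chol(V)) %*% rnorm(m))
  scan_g <- data.frame(measure = paste0("m", 1:m), age = ages,
                       trait_code = trait, var_set = yi, se_var_set = se,
                       lrt_p = 0.5, z_set = 0)
  fit_g <- meta_regress(scan_g, R, random = FALSE, interaction = FALSE)
  X <- cbind(1, ages, trait)
  Vi <- solve(V)
  gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% yi)
  expect_equal(fit_g$coef$estimate, as.numeric(gls), tolerance = 1e-8)
  ## duplicating every row (block-doubled V) leaves the GLS point estimate
  X2 <- rbind(X, X); y2 <- c(yi, yi)
  V2 <- matrix(0, 2 * m, 2 * m)
  V2[1:m, 1:m] <- V; V2[m + 1:m, m + 1:m] <- V
  gls2 <- solve(t(X2) %*% solve(V2) %*% X2, t(X2) %*% solve(V2) %*% y2)
  expect_equal(as.numeric(gls2), as.numeric(gls), tolerance = 1e-10)
})
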
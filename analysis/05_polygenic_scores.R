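#!/usr/bin/env Rscript

## 05 — Polygenic scoring and trait-disorder overlap.
##
## Clumps the two discovery GWAS against the cohort panel, builds
## Z-standardised scores over the threshold grid, and estimates
##   * age-specific cross-sectional associations (uni-dimensional: ADHD-like
##     discovery vs the SDQ-ADHD-like trait; cross-dimensional: ASD-like
##     discovery vs the same trait),
##   * longitudinal mixed-model associations on the untransformed scores
##     (Gaussian with random age slopes for the 0-10 trait; Poisson with
##     random intercepts for the 0-24 trait), with bootstrap CIs,
##   * the polygenic power and genetic-covariance calculations of the
##     closed-form score model at the clinical-scale discovery designs.

library(gcovpipe)

data_dir <- "scratch/analysis"
ck <- readRDS(file.path(data_dir, "cohort.rds"))
measures <- readRDS(file.path(data_dir, "measures.rds"))
spec <- ck$spec
adhd_gwas <- read_sumstats(file.path(data_dir, "adhd_gwas.tsv"))
asd_gwas <- read_sumstats(file.path(data_dir, "asd_gwas.tsv"))

message("clumping (r2 > 0.25, +/-500 kb) and scoring...")
kept_adhd <- clump(adhd_gwas, ck$panel)
kept_asd <- clump(asd_gwas, ck$panel)
message(length(kept_adhd), " / ", length(kept_asd),
        " SNPs retained (ADHD-like / ASD-like)")
sc_adhd <- build_scores(ck$panel, adhd_gwas, kept_adhd)
sc_asd <- build_scores(ck$panel, asd_gwas, kept_asd)

message("age-specific associations with the 0-10 ADHD-like trait...")
cs <- do.call(rbind, lapply(which(spec$trait_of == "adhd"), function(i) {
  uni <- assoc_cross_sectional(sc_adhd, measures[[spec$labels[i]]])
  crx <- assoc_cross_sectional(sc_asd, measures[[spec$labels[i]]])
  uni$discovery <- "adhd_like"; crx$discovery <- "asd_like"
  out <- rbind(uni, crx)
  out$measure <- spec$labels[i]
  out
}))
write.table(cs, "results/05_age_specific_pgs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
at05 <- cs[cs$threshold == 0.5, ]
message(sprintf(
  "at P_T = 0.5: uni-dimensional mean adj R2 = %.4f%%; cross-dimensional = %.4f%%",
  100 * mean(at05$adj_r2[at05$discovery == "adhd_like"]),
  100 * mean(at05$adj_r2[at05$discovery == "asd_like"])))

message("longitudinal mixed models (bootstrap n = 100)...")
lg <- assoc_longitudinal_gaussian(sc_adhd, ck$pheno, "adhd",
                                  threshold = 0.5, n_boot = 100,
                                  seed = 20260406)
message(sprintf(
  "Gaussian: beta_PGS = %.3f (95%% CI %.3f, %.3f), interaction p = %.2f, marginal R2 = %.3f%%",
  lg$beta_pgs, lg$ci_pgs[1], lg$ci_pgs[2], lg$lrt_p_interaction,
  100 * lg$marginal_r2))
lp <- assoc_longitudinal_poisson(sc_adhd, ck$pheno, "scdc",
                                 threshold = 0.5, n_boot = 100,
                                 seed = 20260407)
message(sprintf(
  "Poisson (cross-dimensional): beta_PGS = %.3f (95%% CI %.3f, %.3f)",
  lp$beta_pgs, lp$ci_pgs[1], lp$ci_pgs[2]))
long_tab <- data.frame(
  model = c("gaussian_adhd", "poisson_scdc"),
  beta_pgs = c(lg$beta_pgs, lp$beta_pgs),
  ci_lo = c(lg$ci_pgs[1], lp$ci_pgs[1]),
  ci_hi = c(lg$ci_pgs[2], lp$ci_pgs[2]),
  beta_pgs_by_age = c(lg$beta_pgs_by_age, lp$beta_pgs_by_age),
  lrt_p_interaction = c(lg$lrt_p_interaction, lp$lrt_p_interaction),
  marginal_r2 = c(lg$marginal_r2, lp$marginal_r2))
write.table(long_tab, "results/05_longitudinal_pgs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("closed-form polygenic power / covariance model...")
asd_spec <- polygenic_model_spec(
  h2_discovery = 0.17, genetic_covariance = 0.10 / 2, n_cases = 5305,
  n_controls = 5305, prevalence = 0.01, n_target = 5259, threshold = 0.5)
adhd_spec <- polygenic_model_spec(
  h2_discovery = 0.28, genetic_covariance = 0.10 / 2, n_cases = 4163,
  n_controls = 12040, prevalence = 0.05, n_target = 5551, threshold = 0.5)
inv <- polygenic_covariance_from_r2(adhd_spec, observed_r2 = 0.00084,
                                    target_n = 5000)
model_tab <- data.frame(
  quantity = c("power_cross_dimensional_asd_discovery",
               "power_cross_dimensional_adhd_discovery",
               "covariance_from_r2_0.084pct"),
  value = c(polygenic_power(asd_spec), polygenic_power(adhd_spec),
            inv$covariance),
  ci_lo = c(NA, NA, inv$ci[1]), ci_hi = c(NA, NA, inv$ci[2]))
print(model_tab, digits = 3)
write.table(model_tab, "results/05_polygenic_model.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
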
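#!/usr/bin/env Rscript

## 01 — Simulate the synthetic study cohort.
##
## Builds everything downstream steps need, with known ground truth:
##   * a genotype panel (n = 1500 children x 4000 post-QC SNPs, HWE, 22
##     autosomes) and a PLINK bed/bim/fam export,
##   * a gene annotation (400 autosomal genes) plus a 50-pathway gene-set
##     collection (GMT) in which pathway_01 is truly enriched,
##   * two longitudinal questionnaire traits: an SDQ-ADHD-like 0-10 score at
##     ages 7/10/12/13/17 and an SCDC-like 0-24 score at ages 8/11/14/17,
##     with age-gap-decaying genetic/residual correlations and 25% of the
##     genetic variance driven by pathway_01 genes (+/- 50 kb),
##   * case/control discovery GWAS summary statistics for an ADHD-like
##     disorder (prevalence 0.05, liability SNP-h2 0.28) sharing causal
##     SNPs with the traits, and an ASD-like disorder (prevalence 0.01,
##     liability SNP-h2 0.17) without shared effects.
##
## Bulky intermediates go to scratch/analysis/; small summaries to results/.

library(gcovpipe)

data_dir <- "scratch/analysis"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)
seed <- 20260401

message("simulating genotype panel (1500 x 4000)...")
panel <- simulate_genotypes(1500, 4000, maf_low = 0.05, maf_high = 0.5,
                            seed = seed)
write_plink(panel, file.path(data_dir, "cohort"))

message("simulating annotation and pathway collection...")
ann <- simulate_annotation(panel, 400, mean_length = 8e5, seed = seed + 1)
write_annotation_bed(ann, file.path(data_dir, "genes.bed"))
set.seed(seed + 2)
pathways <- lapply(1:50, function(i) {
  if (i == 1) ann$gene_id[1:20] else sample(ann$gene_id, 20)
})
names(pathways) <- sprintf("pathway_%02d", 1:50)
write_gmt(pathways, file.path(data_dir, "pathways.gmt"))

message("simulating longitudinal traits (9 measures, enriched pathway_01)...")
spec <- trait_sim_spec(n_causal = 800,
                       enriched_set = list(gene_ids = pathways$pathway_01,
                                           fraction = 0.25, flank = 5e4),
                       seed = seed + 3)
pheno <- simulate_longitudinal_traits(panel, spec, ann)
write_phenotypes(pheno, file.path(data_dir, "phenotypes.tsv"))

message("simulating discovery GWAS summary statistics...")
causal <- attr(pheno, "causal")$snp_id
B <- attr(pheno, "effects")
## ADHD-like discovery shares the SDQ-ADHD age-12 architecture (cov 0.10)
adhd_gwas <- simulate_disorder_gwas(
  panel, h2_liability = 0.28, prevalence = 0.05,
  n_cases = 4163, n_controls = 12040, causal_ids = causal,
  seed = seed + 4, trait_effects = B[, "adhd_12"], target_covariance = 0.10)
write_sumstats(adhd_gwas, file.path(data_dir, "adhd_gwas.tsv"))
## ASD-like discovery with disjoint effects (no trait overlap)
asd_gwas <- simulate_disorder_gwas(
  panel, h2_liability = 0.17, prevalence = 0.01,
  n_cases = 5305, n_controls = 5305,
  causal_ids = sample(setdiff(panel$snps$snp_id, causal), 800),
  seed = seed + 5)
write_sumstats(asd_gwas, file.path(data_dir, "asd_gwas.tsv"))

saveRDS(list(panel = panel, ann = ann, pathways = pathways, spec = spec,
             pheno = pheno), file.path(data_dir, "cohort.rds"))

truth <- data.frame(measure = spec$labels, age = spec$ages,
                    trait = spec$trait_of, h2_target = spec$h2,
                    set_fraction = 0.25)
write.table(truth, "results/01_simulation_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("ground truth written to results/01_simulation_truth.tsv")
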
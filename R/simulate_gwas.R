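## Liability-threshold conversion -------------------------------------------
## For a disorder with prevalence K studied in a case/control sample with
## case fraction P, a per-standardised-genotype effect b on the liability
## scale maps to an effect on the (mean-centred) 0/1 observed scale of
##   b_obs = b * z * P(1-P) / (K(1-K)),   z = dnorm(qnorm(1-K)),
## the classic threshold-model transformation. Dividing by Var(y) = P(1-P)
## gives the per-allele linear slope; small-effect log-odds follow as
## slope / (P(1-P)).

#' Liability-to-observed scale factor under the threshold model
#'
#' @param prevalence population prevalence `K` in (0, 0.5).
#' @param case_fraction proportion of cases `P` in the analysed sample.
#' @return multiplier taking a liability-scale standardised-genotype effect to
#'   the 0/1 observed scale in the ascertained sample.
#' @export
liability_to_observed <- function(prevalence, case_fraction) {
  z <- stats::dnorm(stats::qnorm(1 - prevalence))
  z * case_fraction * (1 - case_fraction) / (prevalence * (1 - prevalence))
}

#' Simulate case/control discovery GWAS summary statistics
#'
#' Draws true liability-scale per-SNP effects for a stated causal set and
#' reports observed-scale log-odds estimates with sampling noise at the
#' standard error implied by the design (analytic generation: no discovery
#' genotypes are simulated; the scoring pipeline only consumes effect sizes
#' and p-values). Optionally, effects on a subset of SNPs are drawn
#' correlated with supplied trait effects so that the trait-disorder genetic
#' covariance has a known target value.
#'
#' @param panel a `genotype_panel` (SNP ids, alleles and frequencies).
#' @param h2_liability liability-scale SNP heritability in `[0,1]`.
#' @param prevalence population prevalence in (0, 0.5).
#' @param n_cases,n_controls discovery sample design.
#' @param causal_ids SNP ids carrying the disorder's liability effects.
#' @param seed integer seed.
#' @param trait_effects optional named numeric vector of standardised
#'   liability/trait effects (`names` = SNP ids); together with
#'   `target_covariance` this induces a trait-disorder genetic covariance.
#' @param target_covariance genetic covariance between disorder liability and
#'   the trait on standardised scales (default 0 = independent effects).
#' @return A `data.frame` (class `summary_stats`) with columns `snp_id`,
#'   `allele_effect`, `allele_other`, `effect` (log-odds per effect allele),
#'   `se`, `p_value`, `allele_freq`, plus attribute `true_effects`
#'   (standardised liability-scale effects).
#' @export
simulate_disorder_gwas <- function(panel, h2_liability, prevalence, n_cases,
                                   n_controls, causal_ids, seed = 1,
                                   trait_effects = NULL,
                                   target_covariance = 0) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (prevalence <= 0 || prevalence >= 0.5)
    stop("prevalence must lie in (0, 0.5)", call. = FALSE)
  if (h2_liability < 0 || h2_liability > 1)
    stop("h2_liability must lie in [0,1]", call. = FALSE)
  miss <- setdiff(causal_ids, panel$snps$snp_id)
  if (length(miss))
    stop("causal ids absent from panel: ", paste(utils::head(miss, 3),
         collapse = ", "), call. = FALSE)
  set.seed(seed)

  snps <- panel$snps
  m <- nrow(snps)
  k <- length(causal_ids)
  b <- stats::setNames(numeric(m), snps$snp_id)

  if (k > 0 && h2_liability > 0) {
    if (!is.null(trait_effects) && target_covariance != 0) {
      shared <- intersect(causal_ids, names(trait_effects))
      if (!length(shared))
        stop("target_covariance requested but no causal SNP overlaps ",
             "trait_effects", call. = FALSE)
      a <- trait_effects[shared]
      v_sh <- sum(a^2)
      if (target_covariance^2 > h2_liability * v_sh)
        stop("target_covariance^2 exceeds h2_liability * shared trait ",
             "variance; infeasible", call. = FALSE)
      ## regression construction: b = (c/v_sh) a + independent remainder
      b[shared] <- (target_covariance / v_sh) * a
      used <- sum(b[shared]^2)
      rest <- setdiff(causal_ids, shared)
      resid_var <- h2_liability - used
      spread <- c(shared, rest)   # top up variance over the whole causal set
      noise <- stats::rnorm(length(spread), 0, sqrt(resid_var / length(spread)))
      b[spread] <- b[spread] + noise
    } else {
      b[causal_ids] <- stats::rnorm(k, 0, sqrt(h2_liability / k))
    }
  }

  n1 <- n_cases + n_controls
  P <- n_cases / n1
  l2o <- liability_to_observed(prevalence, P)
  het <- 2 * snps$allele_freq * (1 - snps$allele_freq)
  ## per-allele log-odds: observed-scale slope / Var(y), de-standardised
  beta_logodds <- b * l2o / (P * (1 - P)) / sqrt(het)
  se <- 1 / sqrt(n1 * P * (1 - P) * het)
  est <- beta_logodds + stats::rnorm(m, 0, se)
  pval <- 2 * stats::pnorm(-abs(est / se))

  out <- data.frame(snp_id = snps$snp_id, allele_effect = snps$allele_alt,
                    allele_other = snps$allele_ref, effect = est, se = se,
                    p_value = pval, allele_freq = snps$allele_freq,
                    stringsAsFactors = FALSE)
  attr(out, "true_effects") <- b
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write summary statistics to TSV (SNP, A1, A2, BETA, SE, P, FRQ)
#' @param sumstats a `summary_stats` data.frame.
#' @param path output file.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$snp_id, A1 = sumstats$allele_effect,
                    A2 = sumstats$allele_other, BETA = sumstats$effect,
                    SE = sumstats$se, P = sumstats$p_value,
                    FRQ = sumstats$allele_freq)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read summary statistics from TSV (SNP, A1, A2, BETA or OR, SE, P, FRQ)
#' @param path input file; an `OR` column is log-transformed to `BETA`.
#' @export
read_sumstats <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  eff <- if ("BETA" %in% names(x)) x$BETA else log(x$OR)
  out <- data.frame(snp_id = x$SNP, allele_effect = x$A1, allele_other = x$A2,
                    effect = eff, se = x$SE, p_value = x$P,
                    allele_freq = x$FRQ, stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}
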
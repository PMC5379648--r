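#' Specification for simulating two longitudinal correlated traits
#'
#' Encodes the ground truth for the synthetic cohort: two labelled traits
#' measured at several ages, per-measure SNP heritability targets, genetic and
#' residual correlation matrices across all measures, the causal SNP count,
#' an optional enriched gene set (a stated fraction of genetic variance drawn
#' from SNPs within set genes +/- a flank), and raw-score emulation parameters.
#'
#' Raw scores are produced by a binomial quantile map: the default
#' `Binomial(10, 0.25)` and `Binomial(24, 0.12)` maps emulate positively
#' skewed, leptokurtic questionnaire scores on 0-10 and 0-24 scales without
#' modelling item-level responses.
#'
#' The default ages are 7, 10, 12, 13, 17 (trait "adhd", an SDQ-ADHD-like
#' 0-10 score) and 8, 11, 14, 17 (trait "scdc", an SCDC-like 0-24 score).
#' Default correlation matrices decay exponentially with age gap.
#'
#' @param traits named list of two trait descriptors, each a list with `ages`
#'   (numeric vector, years), `h2` (per-measure SNP-h2 targets in `[0,1]`),
#'   `max_score` (integer raw-score maximum) and `skew_p` (binomial success
#'   probability of the quantile map).
#' @param genetic_corr,residual_corr correlation matrices across all measures
#'   (ordered trait 1 measures, then trait 2); if `NULL`, exponential
#'   age-gap-decay defaults are built (see Details).
#' @param n_causal number of causal SNPs.
#' @param enriched_set optional list(`gene_ids`, `fraction`, `flank`):
#'   fraction of genetic variance attributed to causal SNPs inside the set
#'   genes +/- flank bp.
#' @param sex_effect,age_effect latent-scale covariate effects attached to the
#'   simulated scores (removed again downstream by residualisation).
#' @param seed integer seed.
#' @return A `trait_sim_spec` object.
#' @export
trait_sim_spec <- function(traits = NULL, genetic_corr = NULL,
                           residual_corr = NULL, n_causal = 1000,
                           enriched_set = NULL, sex_effect = 0.2,
                           age_effect = 0.02, seed = 1) {
  if (is.null(traits)) {
    traits <- list(
      adhd = list(ages = c(7, 10, 12, 13, 17),
                  h2 = c(0.10, 0.15, 0.19, 0.18, 0.12),
                  max_score = 10L, skew_p = 0.25),
      scdc = list(ages = c(8, 11, 14, 17),
                  h2 = c(0.24, 0.16, 0.08, 0.45),
                  max_score = 24L, skew_p = 0.12))
  }
  if (length(traits) != 2 || is.null(names(traits)))
    stop("traits must be a named list of two traits", call. = FALSE)
  ages <- unname(unlist(lapply(traits, `[[`, "ages")))
  h2 <- unname(unlist(lapply(traits, `[[`, "h2")))
  if (any(h2 < 0 | h2 > 1)) stop("h2 targets must lie in [0,1]", call. = FALSE)
  m <- length(ages)
  labels <- unlist(mapply(function(nm, tr) paste0(nm, "_", tr$ages),
                          names(traits), traits, SIMPLIFY = FALSE))
  trait_of <- rep(names(traits), vapply(traits, function(t) length(t$ages), 1L))

  decay_corr <- function(scale, tau) {
    R <- scale * exp(-abs(outer(ages, ages, `-`)) / tau)
    # extra shrinkage across traits keeps cross-trait below within-trait
    cross <- outer(trait_of, trait_of, `!=`)
    R[cross] <- 0.95 * R[cross]
    diag(R) <- 1
    R
  }
  if (is.null(genetic_corr)) genetic_corr <- decay_corr(0.95, 15)
  if (is.null(residual_corr)) residual_corr <- decay_corr(0.50, 10)
  check_corr_matrix(genetic_corr, "genetic_corr")
  check_corr_matrix(residual_corr, "residual_corr")
  if (nrow(genetic_corr) != m || nrow(residual_corr) != m)
    stop("correlation matrices must be ", m, " x ", m, call. = FALSE)
  if (!is.null(enriched_set)) {
    f <- enriched_set$fraction
    if (is.null(f) || f < 0 || f > 1)
      stop("enrichment fraction must lie in [0,1]", call. = FALSE)
    enriched_set$flank <- enriched_set$flank %||% 5e4
  }
  structure(list(traits = traits, labels = labels, trait_of = trait_of,
                 ages = ages, h2 = h2, genetic_corr = genetic_corr,
                 residual_corr = residual_corr, n_causal = n_causal,
                 enriched_set = enriched_set, sex_effect = sex_effect,
                 age_effect = age_effect, seed = seed),
            class = "trait_sim_spec")
}

#' Simulate longitudinal correlated trait scores over a genotype panel
#'
#' For each measure t the latent value is `y_t = g_t + e_t`, where
#' `g_t = sum_i beta_ti z_i` over standardised causal dosages. Per-SNP effect
#' vectors across measures are multivariate normal with the spec's genetic
#' correlation matrix and scales chosen so `Var(g_t)` meets the per-measure
#' h2 target; residual vectors follow the residual correlation matrix scaled
#' to `1 - h2`. If an enriched gene set is specified, the stated fraction of
#' each `Var(g_t)` comes from causal SNPs inside set genes plus flank.
#' Latent values are mapped to integer raw scores by the quantile map of a
#' right-skewed binomial, and covariates (sex, mean-centred age jitter, two
#' ancestry-like PCs with no true effect) are attached.
#'
#' @param panel a `genotype_panel`.
#' @param spec a `trait_sim_spec`.
#' @param annotation a `gene_annotation`; required when `spec$enriched_set`
#'   is given.
#' @return A long-format `data.frame` (class `phenotype_table`) with columns
#'   `iid`, `trait`, `age_band`, `age`, `sex`, `score`, `pc1`, `pc2` and
#'   `latent` (the underlying continuous value, kept for validation), plus
#'   attributes `causal` (data.frame of causal SNP ids and per-measure
#'   standardised effects) and `labels`.
#' @export
simulate_longitudinal_traits <- function(panel, spec, annotation = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(spec, "trait_sim_spec"))
  m_snps <- nrow(panel$snps)
  if (spec$n_causal > m_snps)
    stop("causal SNP count exceeds panel SNPs", call. = FALSE)
  set.seed(spec$seed)
  n <- length(panel$sample_ids)
  T <- length(spec$labels)

  ## choose causal SNPs (enrichment-aware)
  if (!is.null(spec$enriched_set)) {
    if (is.null(annotation))
      stop("annotation required for an enriched gene set", call. = FALSE)
    part <- partition_by_geneset(panel, annotation,
                                 spec$enriched_set$gene_ids,
                                 flank = spec$enriched_set$flank)
    f <- spec$enriched_set$fraction
    k_set <- min(length(part$set_snp_ids), max(1L, round(spec$n_causal * f)))
    k_out <- spec$n_causal - k_set
    causal_ids <- c(sample(part$set_snp_ids, k_set),
                    sample(part$noset_snp_ids, k_out))
    in_set <- c(rep(TRUE, k_set), rep(FALSE, k_out))
  } else {
    causal_ids <- sample(panel$snps$snp_id, spec$n_causal)
    in_set <- rep(FALSE, spec$n_causal)
    f <- NULL
  }
  K <- length(causal_ids)

  ## per-SNP effects: rows ~ MVN(0, G), columns scaled to the h2 targets,
  ## with set SNPs carrying the enrichment fraction of genetic variance
  B <- rmvn(K, spec$genetic_corr)
  w <- rep(1 / K, K)
  if (!is.null(f) && any(in_set)) {
    k_set <- sum(in_set)
    w[in_set] <- f / k_set
    w[!in_set] <- (1 - f) / max(1L, K - k_set)
  }
  B <- B * sqrt(w)                       # E[sum_i beta_ti^2] = 1 per measure
  B <- sweep(B, 2, sqrt(spec$h2), `*`)

  Z <- standardize_dosages(panel$dosages[, causal_ids, drop = FALSE])$W
  G <- Z %*% B                           # n x T genetic values
  E <- rmvn(n, spec$residual_corr)
  E <- sweep(E, 2, sqrt(pmax(0, 1 - spec$h2)), `*`)

  sex <- stats::rbinom(n, 1, 0.5)
  pc1 <- stats::rnorm(n); pc2 <- stats::rnorm(n)

  rows <- vector("list", T)
  for (t in seq_len(T)) {
    tr <- spec$trait_of[t]
    band <- spec$ages[t]
    age_jit <- stats::rnorm(n, 0, 0.15)          # mean-centred exact-age jitter
    age <- band + age_jit
    latent <- unname(G[, t]) + E[, t] +
      spec$sex_effect * (sex - 0.5) + spec$age_effect * age_jit
    tinfo <- spec$traits[[tr]]
    ## quantile map: monotone in the latent value, right-skewed marginal
    u <- (rank(latent, ties.method = "average") - 0.5) / n
    score <- stats::qbinom(u, tinfo$max_score, tinfo$skew_p)
    rows[[t]] <- data.frame(iid = panel$sample_ids, trait = tr,
                            age_band = band, age = age, sex = sex,
                            score = as.integer(score), pc1 = pc1, pc2 = pc2,
                            latent = latent, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "causal") <- data.frame(snp_id = causal_ids, in_set = in_set,
                                    stringsAsFactors = FALSE)
  rownames(B) <- causal_ids
  colnames(B) <- spec$labels
  attr(out, "effects") <- B
  attr(out, "labels") <- spec$labels
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a phenotype table to TSV
#'
#' Columns `iid`, `trait`, `age_band`, `age`, `sex`, `score` (the `latent`,
#' `pc1`, `pc2` validation columns are included when present).
#' @param table a `phenotype_table`.
#' @param path output file.
#' @export
write_phenotypes <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
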
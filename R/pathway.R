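#' Gene-set partitioned heritability scan across measures
#'
#' For each pathway and each measure, partitions the panel's SNPs by the
#' pathway's genes (plus flank), builds set/noset GRMs once per pathway, and
#' runs [reml_partitioned()]. Pathways with zero in-set SNPs are skipped with
#' a warning.
#'
#' @param measures named list of `transformed_measure`s sharing one (pruned)
#'   id set; names are used as measure labels.
#' @param panel a `genotype_panel` restricted to the analysis sample.
#' @param annotation a `gene_annotation`.
#' @param pathways named list of gene-id vectors.
#' @param flank flank in bp around each gene (default 50 kb).
#' @param ages,trait_codes optional numeric vectors (one per measure) carried
#'   into the scan rows for the meta-regression (age at assessment, and
#'   trait coded 0/1).
#' @param constrain passed to [reml_partitioned()]; the default `FALSE`
#'   yields signed, null-calibrated evidence for the meta-analysis.
#' @return list of `pathway_scan` objects, one per retained pathway: each a
#'   data.frame with one row per measure (`measure`, `age`, `trait_code`,
#'   `var_set`, `se_var_set`, `lrt_p`, `z_set`) plus attribute `pathway_id`.
#' @export
pathway_scan <- function(measures, panel, annotation, pathways, flank = 5e4,
                         ages = NULL, trait_codes = NULL, constrain = FALSE) {
  stopifnot(length(pathways) >= 1, !is.null(names(pathways)))
  labels <- names(measures)
  ids <- measures[[1]]$individual_ids
  for (m in measures)
    if (!setequal(m$individual_ids, ids))
      stop("all measures must share one id set (prune first)", call. = FALSE)
  out <- list()
  for (pw in names(pathways)) {
    part <- partition_by_geneset(panel, annotation, pathways[[pw]], flank)
    if (!length(part$set_snp_ids)) {
      warning("pathway ", pw, " has zero in-set SNPs; skipped")
      next
    }
    if (!length(part$noset_snp_ids)) {
      warning("pathway ", pw, " covers every SNP; skipped")
      next
    }
    g_set <- compute_grm(panel, part$set_snp_ids)
    g_noset <- compute_grm(panel, part$noset_snp_ids)
    rows <- lapply(seq_along(measures), function(i) {
      fit <- reml_partitioned(measures[[i]], g_set, g_noset,
                              constrain = constrain)
      data.frame(measure = labels[i],
                 age = if (is.null(ages)) NA_real_ else ages[i],
                 trait_code = if (is.null(trait_codes)) NA_real_
                              else trait_codes[i],
                 var_set = fit$var_set, se_var_set = fit$se_var_set,
                 lrt_p = fit$lrt_p_set, z_set = fit$z_set,
                 stringsAsFactors = FALSE)
    })
    scan <- do.call(rbind, rows)
    attr(scan, "pathway_id") <- pw
    class(scan) <- c("pathway_scan", "data.frame")
    out[[pw]] <- scan
  }
  out
}

#' Combine correlated per-measure set tests with a homogeneity statistic
#'
#' Per-measure one-sided evidence is expressed as a z-score and combined by
#' the quadratic form `Q = z' R^-1 z`, where `R` is the phenotypic
#' correlation matrix among the measures (a working approximation to the
#' correlation of the test statistics); `p_meta` refers `Q` to a chi-squared
#' distribution with one degree of freedom per measure, and a Bonferroni
#' adjustment over the pathway collection is attached.
#'
#' The z-scores are taken from the scan's signed roots (`z_set`) when
#' present; otherwise they are recovered from the one-sided boundary-mixture
#' p-values as `z = qnorm(1 - p)` (exact inversion of the 50:50
#' chi2_0/chi2_1 survival function for p <= 1/2). `R` is regularised by an
#' eigenvalue floor before inversion, with a message if flooring occurred.
#'
#' @param scan a `pathway_scan` (rows ordered as `pheno_corr` labels).
#' @param pheno_corr a `correlation_matrix` across the scan's measures.
#' @param n_pathways Bonferroni denominator (default 50, the hallmark
#'   collection size).
#' @param eig_floor eigenvalue floor for `R` (default 1e-6).
#' @return list of class `meta_combined`: `Q`, `df`, `p_meta`, `p_adjusted`,
#'   `z`, `n_pathways`.
#' @export
combine_correlated <- function(scan, pheno_corr, n_pathways = 50,
                               eig_floor = 1e-6) {
  R <- if (inherits(pheno_corr, "correlation_matrix")) pheno_corr$values
       else pheno_corr
  labs <- scan$measure
  if (!is.null(colnames(R))) {
    if (!all(labs %in% colnames(R)))
      stop("pheno_corr labels do not match the scan's measures",
           call. = FALSE)
    R <- R[labs, labs, drop = FALSE]
  } else if (nrow(R) != nrow(scan)) {
    stop("pheno_corr dimension does not match the scan", call. = FALSE)
  }
  z <- if (!is.null(scan$z_set) && all(is.finite(scan$z_set))) scan$z_set
       else stats::qnorm(1 - pmin(pmax(scan$lrt_p, 1e-300), 1 - 1e-16))
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (any(ev$values < eig_floor)) {
    message("correlation matrix regularised: ",
            sum(ev$values < eig_floor), " eigenvalue(s) floored at ",
            eig_floor)
    ev$values <- pmax(ev$values, eig_floor)
  }
  Rinv <- ev$vectors %*% (t(ev$vectors) / ev$values)
  Q <- as.numeric(t(z) %*% Rinv %*% z)
  df <- length(z)
  p_meta <- stats::pchisq(Q, df = df, lower.tail = FALSE)
  structure(list(Q = Q, df = df, p_meta = p_meta,
                 p_adjusted = min(1, p_meta * n_pathways), z = z,
                 n_pathways = n_pathways),
            class = "meta_combined")
}

#' Matched-gene-set permutation for a pathway's combined statistic
#'
#' Generates `n_perm` random gene sets matched to the target pathway on gene
#' count per gene-length decile bin (bins from the annotation-wide length
#' distribution) and on total gene length (within +/- `length_tol`), scans
#' and combines each exactly like the target, and reports the add-one
#' empirical p-value `(1 + #{Q_perm >= Q_obs}) / (n_perm + 1)`.
#'
#' @param panel,annotation,measures,flank,pheno_corr as in [pathway_scan()]
#'   and [combine_correlated()].
#' @param target_genes gene ids of the observed pathway.
#' @param n_perm number of matched random sets (default 200).
#' @param seed integer seed for the sampled sets.
#' @param length_tol relative tolerance on total gene length (default 0.10).
#' @param ages,trait_codes,constrain passed through to the scans.
#' @param max_tries resampling attempts per permutation before erroring.
#' @return list of class `matched_permutation`: `empirical_p`, `Q_obs`,
#'   `Q_perm` (vector), `n_perm`.
#' @export
matched_permutation <- function(panel, annotation, target_genes, measures,
                                pheno_corr, n_perm = 200, seed = 1,
                                flank = 5e4, length_tol = 0.10,
                                ages = NULL, trait_codes = NULL,
                                constrain = FALSE, max_tries = 200) {
  set.seed(seed)
  obs_scan <- pathway_scan(measures, panel, annotation,
                           pathways = list(target = target_genes),
                           flank = flank, ages = ages,
                           trait_codes = trait_codes,
                           constrain = constrain)$target
  Q_obs <- combine_correlated(obs_scan, pheno_corr)$Q

  len <- annotation$end - annotation$start + 1
  names(len) <- annotation$gene_id
  breaks <- unique(stats::quantile(len, probs = seq(0, 1, 0.1)))
  bin <- cut(len, breaks = breaks, include.lowest = TRUE)
  target_bin <- bin[match(target_genes, annotation$gene_id)]
  need <- table(target_bin)
  pool_ids <- setdiff(annotation$gene_id, target_genes)
  pool_bin <- bin[match(pool_ids, annotation$gene_id)]
  short <- names(need)[need > 0 &
                       need > table(factor(pool_bin, levels = levels(bin)))[names(need)]]
  if (length(short))
    stop("matching infeasible: not enough genes outside the pathway in ",
         "length bin(s) ", paste(short, collapse = ", "), call. = FALSE)
  target_total <- sum(len[target_genes])

  draw_set <- function() {
    for (t in seq_len(max_tries)) {
      cand <- unlist(lapply(names(need)[need > 0], function(b) {
        sample(pool_ids[pool_bin == b], need[[b]])
      }), use.names = FALSE)
      if (abs(sum(len[cand]) - target_total) <= length_tol * target_total)
        return(cand)
    }
    stop("matching infeasible: no sampled set met the total-length ",
         "tolerance after ", max_tries, " tries", call. = FALSE)
  }

  Q_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    genes_i <- draw_set()
    scan_i <- pathway_scan(measures, panel, annotation,
                           pathways = list(perm = genes_i), flank = flank,
                           ages = ages, trait_codes = trait_codes,
                           constrain = constrain)$perm
    Q_perm[i] <- combine_correlated(scan_i, pheno_corr)$Q
  }
  structure(list(empirical_p = (1 + sum(Q_perm >= Q_obs)) / (n_perm + 1),
                 Q_obs = Q_obs, Q_perm = Q_perm, n_perm = n_perm),
            class = "matched_permutation")
}

#' Read gene sets from a GMT file
#'
#' One set per line: set name, description, then gene ids, tab-separated.
#' @param path GMT file.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' Write gene sets to a GMT file
#' @param sets named list of gene-id vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Random-effects meta-regression of set variance on age and trait
#'
#' Regresses per-measure set variance estimates on age at assessment and a
#' 0/1 trait code, with a random intercept per measure (between-measure
#' variance tau2 by REML) and a known sampling covariance matrix
#' `V = D R D`, where `D = diag(se_var_set)` and `R` is the phenotypic
#' correlation among the measures — the working approximation for
#' correlated estimates from overlapping samples. The trait-by-age
#' interaction is tested by a maximum-likelihood LRT between nested
#' fixed-effect specifications.
#'
#' @param scan a `pathway_scan` with `age` and `trait_code` filled in.
#' @param pheno_corr a `correlation_matrix` across the scan's measures.
#' @param random include the random intercept (default TRUE; FALSE gives the
#'   fixed-effects generalised-least-squares fit, tau2 = 0).
#' @param interaction also fit and test the trait-by-age interaction
#'   (default TRUE).
#' @param eig_floor eigenvalue floor applied to `R` before building `V`.
#' @return list of class `meta_regression`: coefficient table `coef`
#'   (estimate, se, z, p for intercept, age, trait), `tau2`,
#'   `beta_interaction`, `lrt_p_interaction`, and the underlying metafor
#'   fits.
#' @export
meta_regress <- function(scan, pheno_corr, random = TRUE, interaction = TRUE,
                         eig_floor = 1e-6) {
  if (nrow(scan) < 4 || length(unique(scan$trait_code)) < 2)
    stop("meta-regression needs >= 4 measures spanning both traits",
         call. = FALSE)
  R <- if (inherits(pheno_corr, "correlation_matrix")) pheno_corr$values
       else pheno_corr
  if (!is.null(colnames(R))) R <- R[scan$measure, scan$measure]
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (any(ev$values < eig_floor)) {
    message("sampling correlation regularised: ",
            sum(ev$values < eig_floor), " eigenvalue(s) floored")
    ev$values <- pmax(ev$values, eig_floor)
    R <- ev$vectors %*% (t(ev$vectors) * ev$values)
  }
  D <- diag(scan$se_var_set)
  V <- D %*% R %*% D
  dat <- data.frame(yi = scan$var_set, age = scan$age,
                    trait = scan$trait_code, measure = scan$measure)
  random_spec <- if (random) ~ 1 | measure else NULL
  fit_main <- metafor::rma.mv(yi, V, mods = ~ age + trait,
                              random = random_spec, data = dat,
                              method = "REML", sparse = FALSE)
  coefs <- data.frame(term = rownames(fit_main$beta),
                      estimate = as.numeric(fit_main$beta),
                      se = fit_main$se, z = fit_main$zval, p = fit_main$pval)
  tau2 <- if (random) sum(fit_main$sigma2) else 0
  beta_int <- NA_real_; se_int <- NA_real_; lrt_p_int <- NA_real_
  if (interaction) {
    fit0 <- metafor::rma.mv(yi, V, mods = ~ age + trait,
                            random = random_spec, data = dat, method = "ML",
                            sparse = FALSE)
    fit1 <- metafor::rma.mv(yi, V, mods = ~ age * trait,
                            random = random_spec, data = dat, method = "ML",
                            sparse = FALSE)
    lrt <- max(0, 2 * (stats::logLik(fit1) - stats::logLik(fit0)))
    lrt_p_int <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    fit1r <- metafor::rma.mv(yi, V, mods = ~ age * trait,
                             random = random_spec, data = dat,
                             method = "REML", sparse = FALSE)
    k <- length(fit1r$beta)
    beta_int <- as.numeric(fit1r$beta)[k]
    se_int <- fit1r$se[k]
  }
  structure(list(coef = coefs, tau2 = tau2, beta_interaction = beta_int,
                 se_interaction = se_int, lrt_p_interaction = lrt_p_int,
                 fit = fit_main),
            class = "meta_regression")
}
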
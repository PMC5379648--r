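#' Specification of a polygenic-score power / covariance model
#'
#' Describes the discovery GWAS design, the target sample, and the genetic
#' architecture for the closed-form polygenic-score model: per-SNP effects on
#' the discovery trait are normal over the causal SNPs, effect estimates
#' carry the design-implied sampling error, SNPs are selected into the score
#' by a p-value threshold, and the expected squared correlation between the
#' weighted score and the target trait follows from normal selection
#' moments. A binary discovery trait is handled on the liability scale via
#' the threshold-model transformation at the stated prevalence
#' (see [liability_to_observed()]).
#'
#' @param n_snp number of independent score SNPs (post-clumping scale);
#'   default 150000.
#' @param n_causal number of causal SNPs among them (default 100000); the
#'   remaining `n_snp - n_causal` SNPs carry estimation noise only.
#' @param h2_discovery (liability-scale) SNP heritability of the discovery
#'   trait.
#' @param genetic_covariance genetic covariance between discovery liability
#'   and the target trait, both on standardised scales.
#' @param n_cases,n_controls discovery design (binary discovery); or supply
#'   `n_discovery` with `binary = FALSE` for a quantitative discovery trait.
#' @param prevalence population prevalence of the binary discovery trait.
#' @param n_target target sample size (quantitative target trait).
#' @param h2_target optional target-trait SNP heritability; when supplied the
#'   constraint `genetic_covariance^2 <= h2_discovery * h2_target` is
#'   enforced.
#' @param threshold score p-value threshold `P_T` in (0.001, 1].
#' @param alpha type I error rate of the target association test.
#' @param binary is the discovery trait binary (default TRUE)?
#' @param n_discovery total discovery n for a quantitative discovery trait.
#' @return list of class `polygenic_model_spec`.
#' @export
polygenic_model_spec <- function(n_snp = 150000, n_causal = 100000,
                                 h2_discovery, genetic_covariance = NA,
                                 n_cases = NULL, n_controls = NULL,
                                 prevalence = NULL, n_target,
                                 h2_target = NULL, threshold = 0.5,
                                 alpha = 0.05, binary = TRUE,
                                 n_discovery = NULL) {
  if (binary) {
    stopifnot(!is.null(n_cases), !is.null(n_controls), !is.null(prevalence))
    if (prevalence <= 0 || prevalence >= 1)
      stop("prevalence must lie in (0,1)", call. = FALSE)
    n_discovery <- n_cases + n_controls
  } else stopifnot(!is.null(n_discovery))
  if (h2_discovery < 0 || h2_discovery > 1)
    stop("h2_discovery must lie in [0,1]", call. = FALSE)
  if (n_causal > n_snp) stop("n_causal cannot exceed n_snp", call. = FALSE)
  if (threshold <= 0.001 || threshold > 1)
    stop("threshold must lie in (0.001, 1]", call. = FALSE)
  if (!is.na(genetic_covariance) && !is.null(h2_target) &&
      genetic_covariance^2 > h2_discovery * h2_target + 1e-12)
    stop("inconsistent spec: genetic_covariance^2 > h2_discovery * h2_target",
         call. = FALSE)
  structure(list(n_snp = n_snp, n_causal = n_causal,
                 h2_discovery = h2_discovery,
                 genetic_covariance = genetic_covariance,
                 n_cases = n_cases, n_controls = n_controls,
                 prevalence = prevalence, n_discovery = n_discovery,
                 n_target = n_target, h2_target = h2_target,
                 threshold = threshold, alpha = alpha, binary = binary),
            class = "polygenic_model_spec")
}

## E[Z^2 ; |Z| > u] for standard normal
.trunc_second_moment <- function(u) {
  2 * (u * stats::dnorm(u) + stats::pnorm(u, lower.tail = FALSE))
}

#' Expected target-sample R^2 of a polygenic score
#'
#' Closed-form expectation of the squared score-trait correlation in the
#' target sample under the polygenic-score model, for a given genetic
#' covariance. With selection threshold `t = qnorm(1 - P_T/2)` on the
#' discovery z-statistics, effect SNPs (marginal estimate variance
#' `s2 = sigma1^2 + err`) and null SNPs (variance `err`) contribute
#' truncated second moments to the score variance, while the score-trait
#' covariance is proportional to the genetic covariance:
#' `R2 = (cov12 * e(u_eff))^2 / (m_eff s2 e(u_eff) + m_null err e(u_null))`
#' on the observed discovery scale, with `e(u) = E[Z^2; |Z| > u]`.
#'
#' @param spec a `polygenic_model_spec`.
#' @param genetic_covariance optional override of the spec's covariance.
#' @return expected R^2 (proportion of target-trait variance).
#' @export
polygenic_expected_r2 <- function(spec, genetic_covariance = NULL) {
  cv <- genetic_covariance %||% spec$genetic_covariance
  if (is.na(cv)) stop("genetic_covariance must be set", call. = FALSE)
  if (spec$binary) {
    P <- spec$n_cases / spec$n_discovery
    l2o <- liability_to_observed(spec$prevalence, P)
    vg1 <- spec$h2_discovery * l2o^2
    cov12 <- cv * l2o
    var_y1 <- P * (1 - P)
  } else {
    vg1 <- spec$h2_discovery
    cov12 <- cv
    var_y1 <- 1
  }
  err <- var_y1 / spec$n_discovery
  m_eff <- spec$n_causal
  m_null <- spec$n_snp - spec$n_causal
  sigma1_sq <- vg1 / m_eff
  s2 <- sigma1_sq + err
  thr <- stats::qnorm(1 - spec$threshold / 2)       # on the z scale
  u_eff <- thr * sqrt(err / s2)
  e_eff <- .trunc_second_moment(u_eff)
  e_null <- .trunc_second_moment(thr)
  cov_sy <- cov12 * e_eff
  var_s <- m_eff * s2 * e_eff + m_null * err * e_null
  as.numeric(cov_sy^2 / var_s)
}

#' Power of the target-sample polygenic score association test
#'
#' Converts the model's expected R^2 into the non-centrality of the 1-df
#' score-trait association test, `ncp = n_target R2 / (1 - R2)`, and
#' returns the power at the spec's alpha. With zero genetic covariance the
#' power equals alpha exactly.
#'
#' @param spec a `polygenic_model_spec` with `genetic_covariance` set.
#' @return power in `[0, 1]`.
#' @export
polygenic_power <- function(spec) {
  r2 <- polygenic_expected_r2(spec)
  ncp <- spec$n_target * r2 / (1 - r2)
  crit <- stats::qchisq(1 - spec$alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Genetic covariance implied by an observed polygenic-score R^2
#'
#' Inverts the forward model: the expected R^2 is proportional to the
#' squared genetic covariance with a covariance-free score variance, so the
#' inversion is closed-form,
#' `cov = sqrt(r2_obs * var_S) / (liab2obs * e(u_eff))`. The 95% CI is
#' propagated from the sampling distribution of the observed R^2 at the
#' target sample size (non-central chi-squared approximation,
#' `Var(R2_hat) ~ (2 + 4 ncp) / n^2`), with a one-sided interval when the
#' observed R^2 falls below the model's noise floor.
#'
#' @param spec a `polygenic_model_spec` (its `genetic_covariance` is
#'   ignored).
#' @param observed_r2 observed proportion of target-trait variance explained
#'   (e.g. adjusted or marginal regression R^2), in `[0, 1)`.
#' @param target_n target sample size behind `observed_r2` (defaults to the
#'   spec's `n_target`).
#' @return list: `covariance`, `ci` (length-2), `se`, `expected_r2_check`.
#' @export
polygenic_covariance_from_r2 <- function(spec, observed_r2,
                                         target_n = spec$n_target) {
  if (observed_r2 < 0 || observed_r2 >= 1)
    stop("observed_r2 must lie in [0, 1)", call. = FALSE)
  invert <- function(r2) {
    if (r2 <= 0) return(0)
    ## R2(c) = (k c)^2 / var_s with k, var_s covariance-free
    r2_unit <- polygenic_expected_r2(spec, genetic_covariance = 1)
    sqrt(r2 / r2_unit)
  }
  est <- invert(observed_r2)
  ncp <- target_n * observed_r2 / (1 - observed_r2)
  se_r2 <- sqrt(2 + 4 * ncp) / target_n
  lo_r2 <- max(0, observed_r2 - 1.96 * se_r2)
  hi_r2 <- observed_r2 + 1.96 * se_r2
  ci <- c(invert(lo_r2), invert(hi_r2))
  se <- if (est > 0 && observed_r2 > 0) est * se_r2 / (2 * observed_r2)
        else (ci[2] - ci[1]) / (2 * 1.96)
  list(covariance = est, ci = ci, se = se,
       expected_r2_check = polygenic_expected_r2(spec,
                                                 genetic_covariance = est))
}
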
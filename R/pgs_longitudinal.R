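## Longitudinal PGS-trait association under mixed models --------------------

## internal: individual-level nonparametric bootstrap of a fitted refit_fun
boot_betas <- function(ids, refit_fun, n_boot, seed) {
  set.seed(seed)
  uids <- unique(ids)
  out <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    take <- sample(uids, length(uids), replace = TRUE)
    out[b, ] <- refit_fun(take)
  }
  out
}

#' Longitudinal Gaussian mixed-model PGS association
#'
#' Regresses repeatedly measured raw trait scores on a polygenic score with
#' fixed effects for PGS, sex and age at assessment, and random slopes (for
#' age) and intercepts per individual (REML fit via lme4). The PGS-by-age
#' interaction is assessed by a maximum-likelihood LRT between nested
#' models. Confidence intervals for the PGS effect are parametric bootstrap
#' intervals over individuals (estimate +/- 1.96 x bootstrap SD; percentile
#' intervals available via `ci_type`), resampling individuals with all their
#' measurement occasions. The marginal R^2 is the fixed-effects share of
#' total variance, `var_fixed / (var_fixed + var_random + var_residual)`.
#'
#' @param scores a `polygenic_scores` object.
#' @param raw_scores a `phenotype_table` (long format, untransformed scores).
#' @param trait trait label within `raw_scores`.
#' @param threshold which score threshold to use (default 0.5).
#' @param n_boot bootstrap replicates (default 500; `n_boot = 1` yields a
#'   degenerate, flagged interval).
#' @param seed bootstrap seed.
#' @param ci_type `"parametric"` (normal approximation) or `"percentile"`.
#' @return list of class `pgs_longitudinal`: `beta_pgs`, `ci_pgs`,
#'   `beta_pgs_by_age`, `ci_pgs_by_age`, `lrt_p_interaction`, `marginal_r2`,
#'   `model_family`, `n_individuals`, `degenerate_ci` flag.
#' @export
assoc_longitudinal_gaussian <- function(scores, raw_scores, trait,
                                        threshold = 0.5, n_boot = 500,
                                        seed = 1,
                                        ci_type = c("parametric",
                                                    "percentile")) {
  ci_type <- match.arg(ci_type)
  dat <- prep_longitudinal(scores, raw_scores, trait, threshold)
  fit <- lme4::lmer(score ~ pgs + sex + age + (age | iid), data = dat,
                    REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  if (lme4::isSingular(fit)) {
    message("singular random-effect covariance; refitting with independent ",
            "slopes and intercepts")
    fit <- lme4::lmer(score ~ pgs + sex + age + (age || iid), data = dat,
                      REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
  }
  beta <- lme4::fixef(fit)["pgs"]
  ## interaction by ML LRT
  m0 <- lme4::lmer(score ~ pgs + sex + age + (age | iid), data = dat,
                   REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE))
  m1 <- lme4::lmer(score ~ pgs * age + sex + (age | iid), data = dat,
                   REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE))
  lrt <- max(0, 2 * (stats::logLik(m1) - stats::logLik(m0)))
  lrt_p <- stats::pchisq(lrt, 1, lower.tail = FALSE)
  beta_int <- lme4::fixef(m1)["pgs:age"]

  ## marginal R2: fixed / (fixed + random + residual)
  Xf <- stats::model.matrix(fit) %*% lme4::fixef(fit)
  vf <- stats::var(as.vector(Xf))
  vc <- lme4::VarCorr(fit)
  Zt <- cbind(1, dat$age)
  Sig <- as.matrix(Matrix_bdiag_first(vc))
  vr <- mean(rowSums((Zt %*% Sig) * Zt))
  ve <- attr(vc, "sc")^2
  marg_r2 <- vf / (vf + vr + ve)

  refit <- function(take) {
    idx <- unlist(lapply(take, function(id) which(dat$iid == id)),
                  use.names = FALSE)
    bd <- dat[idx, ]
    bd$iid <- rep(seq_along(take), times = vapply(take, function(id)
      sum(dat$iid == id), 1L))
    bf <- tryCatch(
      lme4::lmer(score ~ pgs * age + sex + (age | iid), data = bd,
                 REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                   check.conv.singular = lme4::.makeCC("ignore", 1e-4))),
      error = function(e) NULL)
    if (is.null(bf)) return(c(NA_real_, NA_real_))
    fe <- lme4::fixef(bf)
    c(fe["pgs"], fe["pgs:age"])
  }
  bb <- boot_betas(dat$iid, refit, n_boot, seed)
  make_ci(beta, beta_int, bb, n_boot, ci_type,
          extra = list(lrt_p_interaction = lrt_p, marginal_r2 = marg_r2,
                       model_family = "gaussian",
                       n_individuals = length(unique(dat$iid)), fit = fit))
}

## first grouping factor's covariance as a matrix (random intercept+slope)
Matrix_bdiag_first <- function(vc) {
  m <- vc[[1]]
  if (nrow(m) == 2) return(m[1:2, 1:2])
  ## diagonal (uncorrelated) double-bar fit: combine the per-term variances
  out <- matrix(0, 2, 2)
  out[1, 1] <- m[1, 1]
  if (length(vc) > 1) out[2, 2] <- vc[[2]][1, 1]
  out
}

prep_longitudinal <- function(scores, raw_scores, trait, threshold) {
  t_idx <- match(threshold, scores$thresholds)
  if (is.na(t_idx)) stop("threshold not present in the score set",
                         call. = FALSE)
  if (!scores$usable[t_idx]) stop("score column unusable at this threshold",
                                  call. = FALSE)
  pgs <- stats::setNames(scores$scores[, t_idx], scores$sample_ids)
  dat <- raw_scores[raw_scores$trait == trait, , drop = FALSE]
  dat <- dat[dat$iid %in% names(pgs), , drop = FALSE]
  dat$pgs <- pgs[dat$iid]
  occ <- table(dat$iid)
  if (mean(occ) < 2)
    warning("fewer than 2 occasions per individual on average")
  dat
}

make_ci <- function(beta, beta_int, bb, n_boot, ci_type, extra) {
  degenerate <- n_boot < 2 || all(!is.finite(bb[, 1])) ||
    stats::sd(bb[, 1], na.rm = TRUE) == 0
  if (degenerate) {
    warning("bootstrap CI degenerate (n_boot = ", n_boot, ")")
    ci <- c(NA_real_, NA_real_); ci_int <- c(NA_real_, NA_real_)
  } else if (ci_type == "parametric") {
    s1 <- stats::sd(bb[, 1], na.rm = TRUE)
    ci <- beta + c(-1.96, 1.96) * s1
    s2 <- stats::sd(bb[, 2], na.rm = TRUE)
    ci_int <- if (is.finite(beta_int)) beta_int + c(-1.96, 1.96) * s2
              else c(NA_real_, NA_real_)
  } else {
    ci <- stats::quantile(bb[, 1], c(0.025, 0.975), na.rm = TRUE)
    ci_int <- stats::quantile(bb[, 2], c(0.025, 0.975), na.rm = TRUE)
  }
  structure(c(list(beta_pgs = as.numeric(beta), ci_pgs = as.numeric(ci),
                   beta_pgs_by_age = as.numeric(beta_int),
                   ci_pgs_by_age = as.numeric(ci_int),
                   n_boot = n_boot, degenerate_ci = degenerate), extra),
            class = "pgs_longitudinal")
}

#' Longitudinal Poisson mixed-model PGS association
#'
#' As [assoc_longitudinal_gaussian()] but for count-like scores: Poisson
#' family with log link, random intercepts only (Laplace approximation via
#' lme4), so the PGS coefficient measures the increase in natural-log scores
#' per standard deviation of the score. No marginal R^2 is reported.
#'
#' @inheritParams assoc_longitudinal_gaussian
#' @export
assoc_longitudinal_poisson <- function(scores, raw_scores, trait,
                                       threshold = 0.5, n_boot = 500,
                                       seed = 1,
                                       ci_type = c("parametric",
                                                   "percentile")) {
  ci_type <- match.arg(ci_type)
  dat <- prep_longitudinal(scores, raw_scores, trait, threshold)
  fit <- lme4::glmer(score ~ pgs + sex + age + (1 | iid), data = dat,
                     family = stats::poisson())
  beta <- lme4::fixef(fit)["pgs"]
  m1 <- lme4::glmer(score ~ pgs * age + sex + (1 | iid), data = dat,
                    family = stats::poisson())
  lrt <- max(0, 2 * (stats::logLik(m1) - stats::logLik(fit)))
  lrt_p <- stats::pchisq(lrt, 1, lower.tail = FALSE)
  beta_int <- lme4::fixef(m1)["pgs:age"]
  refit <- function(take) {
    idx <- unlist(lapply(take, function(id) which(dat$iid == id)),
                  use.names = FALSE)
    bd <- dat[idx, ]
    bd$iid <- rep(seq_along(take), times = vapply(take, function(id)
      sum(dat$iid == id), 1L))
    bf <- tryCatch(suppressWarnings(suppressMessages(
      lme4::glmer(score ~ pgs * age + sex + (1 | iid), data = bd,
                  family = stats::poisson()))),
      error = function(e) NULL)
    if (is.null(bf)) return(c(NA_real_, NA_real_))
    fe <- lme4::fixef(bf)
    c(fe["pgs"], fe["pgs:age"])
  }
  bb <- boot_betas(dat$iid, refit, n_boot, seed)
  make_ci(beta, beta_int, bb, n_boot, ci_type,
          extra = list(lrt_p_interaction = lrt_p, marginal_r2 = NA_real_,
                       model_family = "poisson",
                       n_individuals = length(unique(dat$iid)), fit = fit))
}
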
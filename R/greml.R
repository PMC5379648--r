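## Alignment helper: order a measure's values to a set of sample ids.
align_measure <- function(y, ids) {
  if (inherits(y, "transformed_measure"))
    y <- stats::setNames(y$values, y$individual_ids)
  if (is.null(names(y))) stop("measure must carry individual ids",
                              call. = FALSE)
  miss <- setdiff(names(y), ids)
  if (length(miss))
    stop("measure ids absent from GRM: ", paste(utils::head(miss, 3),
         collapse = ", "), call. = FALSE)
  y
}

#' Univariate GREML: SNP heritability by average-information REML
#'
#' Fits `y ~ N(X beta, A sigma2_g + I sigma2_e)` (X = intercept; covariates
#' are removed beforehand by the transform step) by AI-REML in the GRM
#' eigenbasis, with step-halving/EM fallback, components constrained
#' non-negative (unless `constrain = FALSE`), delta-method standard errors
#' from the inverse average-information matrix, and a likelihood-ratio test
#' of `sigma2_g = 0` against the 50:50 chi2_0/chi2_1 boundary mixture.
#'
#' For rank-transformed traits the phenotypic variance is ~1, so
#' `var_g = sigma2_g / (sigma2_g + sigma2_e)` is the SNP heritability.
#'
#' @param y a `transformed_measure` or named numeric vector.
#' @param grm a `grm` covering the measure's ids.
#' @param constrain constrain variance components to be non-negative
#'   (default TRUE).
#' @param eig optional precomputed `eigen()` of the aligned GRM submatrix
#'   (reused across measures on the same sample).
#' @param max_iter,tol AI-REML iteration cap and log-likelihood tolerance.
#' @return list of class `variance_components`: `sigma2_g`, `sigma2_e`,
#'   `var_g`, `se_var_g`, `loglik_full`, `loglik_null`, `lrt`, `lrt_p`,
#'   `n_used`, `converged`.
#' @export
reml_univariate <- function(y, grm, constrain = TRUE, eig = NULL,
                            max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(grm, "grm"))
  y <- align_measure(y, grm$sample_ids)
  ids <- names(y)
  n <- length(y)
  if (n < 100) warning("n = ", n, " is small for GREML; interpret with care")
  A <- grm$values[ids, ids]
  if (is.null(eig)) eig <- eigen(A, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  yt <- as.vector(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, matrix(1, n, 1))
  vp <- stats::var(y)

  be_full <- make_diag_backend(yt, Xt, list(d, rep(1, n)))
  fit <- reml_ai_fit(be_full, theta0 = c(vp / 2, vp / 2),
                     is_var = c(TRUE, TRUE), constrain = constrain,
                     tol = tol, max_iter = max_iter, scale = vp)
  be_null <- make_diag_backend(yt, Xt, list(rep(1, n)))
  fit0 <- reml_ai_fit(be_null, theta0 = vp, is_var = TRUE, constrain = TRUE,
                      tol = tol, max_iter = max_iter, scale = vp)

  th <- fit$theta
  tot <- sum(th)
  var_g <- th[1] / tot
  grad <- c(th[2], -th[1]) / tot^2
  se <- delta_se(grad, fit$cov)
  lrt <- max(0, 2 * (fit$loglik - fit0$loglik))
  structure(list(sigma2_g = th[1], sigma2_e = th[2], var_g = var_g,
                 se_var_g = se, loglik_full = fit$loglik,
                 loglik_null = fit0$loglik, lrt = lrt,
                 lrt_p = boundary_lrt_p(lrt), n_used = n,
                 converged = fit$converged),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("GREML: Var_g = %.4f (SE %.4f), LRT p = %.3g, n = %d%s\n",
              x$var_g, x$se_var_g, x$lrt_p, x$n_used,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Bivariate GREML: genetic correlation between two measures
#'
#' Estimates `(sigma2_g1, sigma2_g2, cov_g, sigma2_e1, sigma2_e2, cov_e)` for
#' two measures over one GRM and reports the genetic correlation
#' `r_g = cov_g / sqrt(sigma2_g1 sigma2_g2)`, the residual correlation `r_e`,
#' and the standardised genetic covariance
#' `Cov_g = r_g sqrt(h2_1 h2_2)` (exact identity for the reported values).
#' The test of `r_g = 0` refits with the genetic covariance pinned to zero
#' and refers the LRT to a plain chi2_1 (the covariance is unbounded in
#' sign).
#'
#' With complete sample overlap the fit runs in the shared GRM eigenbasis
#' (2x2 blocks, O(n) per iteration); with partial overlap a dense
#' stacked-system fit over all individuals with either trait is used.
#'
#' @param y1,y2 `transformed_measure`s or named vectors.
#' @param grm a `grm` covering both measures.
#' @param constrain constrain variances to be non-negative.
#' @param eig optional precomputed eigen of the aligned GRM (complete-overlap
#'   path only).
#' @param max_iter,tol iteration controls.
#' @return list of class `bivariate_estimate` with `h2_1`, `h2_2`, `cov_g`,
#'   `r_g`, `r_e`, `se_r_g`, `se_cov_g`, `lrt_p_rg0`, `n_overlap`,
#'   `converged`, and the raw component vector `theta`.
#' @export
reml_bivariate <- function(y1, y2, grm, constrain = TRUE, eig = NULL,
                           max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(grm, "grm"))
  y1 <- align_measure(y1, grm$sample_ids)
  y2 <- align_measure(y2, grm$sample_ids)
  ids1 <- names(y1); ids2 <- names(y2)
  complete <- length(ids1) == length(ids2) && setequal(ids1, ids2)
  vp <- (stats::var(y1) + stats::var(y2)) / 2
  theta0 <- c(vp / 2, vp / 2, 0, vp / 2, vp / 2, vp / 10)
  is_var <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  cov_bounds <- list(c(3L, 1L, 2L), c(6L, 4L, 5L))

  if (complete) {
    ids <- ids1
    y2 <- y2[ids]
    n <- length(ids)
    A <- grm$values[ids, ids]
    if (is.null(eig)) eig <- eigen(A, symmetric = TRUE)
    d <- pmax(eig$values, 0)
    y1t <- as.vector(crossprod(eig$vectors, y1))
    y2t <- as.vector(crossprod(eig$vectors, y2))
    u <- as.vector(crossprod(eig$vectors, rep(1, n)))
    backend <- make_block2_backend(y1t, y2t, u, d)
    make_null <- function() {
      ## genetic covariance pinned to zero: wrap the 6-parameter backend
      be <- backend
      list(K = 5L, n_eff = be$n_eff, derivs = function(theta, need_ai = TRUE) {
        full <- be$derivs(c(theta[1:2], 0, theta[3:5]), need_ai)
        if (!is.finite(full$ll) || !need_ai) return(full)
        list(ll = full$ll, score = full$score[-3],
             AI = full$AI[-3, -3, drop = FALSE])
      })
    }
    n_overlap <- n
  } else {
    ids <- union(ids1, ids2)
    A <- grm$values[ids, ids]
    n1 <- length(ids1); n2 <- length(ids2)
    i1 <- match(ids1, ids); i2 <- match(ids2, ids)
    nn <- n1 + n2
    Z1 <- matrix(0, n1, length(ids)); Z1[cbind(seq_len(n1), i1)] <- 1
    Z2 <- matrix(0, n2, length(ids)); Z2[cbind(seq_len(n2), i2)] <- 1
    A11 <- Z1 %*% A %*% t(Z1); A22 <- Z2 %*% A %*% t(Z2)
    A12 <- Z1 %*% A %*% t(Z2)
    pad <- function(M, r0, c0) {
      out <- matrix(0, nn, nn)
      out[r0 + seq_len(nrow(M)), c0 + seq_len(ncol(M))] <- M
      out
    }
    shared <- intersect(ids1, ids2)
    E12 <- matrix(0, n1, n2)
    E12[cbind(match(shared, ids1), match(shared, ids2))] <- 1
    Vg1 <- pad(A11, 0, 0)
    Vg2 <- pad(A22, n1, n1)
    Vgc <- pad(A12, 0, n1); Vgc <- Vgc + t(Vgc)
    Ve1 <- pad(diag(n1), 0, 0)
    Ve2 <- pad(diag(n2), n1, n1)
    Vec <- pad(E12, 0, n1); Vec <- Vec + t(Vec)
    ys <- c(y1, y2)
    X <- cbind(c(rep(1, n1), rep(0, n2)), c(rep(0, n1), rep(1, n2)))
    backend <- make_dense_backend(ys, X, list(Vg1, Vg2, Vgc, Ve1, Ve2, Vec))
    make_null <- function() {
      be0 <- make_dense_backend(ys, X, list(Vg1, Vg2, Ve1, Ve2, Vec))
      be0
    }
    n_overlap <- length(shared)
  }

  fit <- reml_ai_fit(backend, theta0, is_var = is_var,
                     cov_bounds = cov_bounds, constrain = constrain,
                     tol = tol, max_iter = max_iter, scale = vp)
  th <- fit$theta
  names(th) <- c("g1", "g2", "gc", "e1", "e2", "ec")
  v1 <- th["g1"] + th["e1"]; v2 <- th["g2"] + th["e2"]
  h2_1 <- as.numeric(th["g1"] / v1); h2_2 <- as.numeric(th["g2"] / v2)
  floor_val <- reml_constants$var_floor_frac * vp
  at_boundary <- th["g1"] <= floor_val * 1.01 || th["g2"] <= floor_val * 1.01
  if (at_boundary) {
    message("a genetic variance estimate is at the zero boundary; ",
            "r_g is undefined (division by ~0)")
    r_g <- NA_real_; se_rg <- NA_real_
  } else {
    r_g <- as.numeric(th["gc"] / sqrt(th["g1"] * th["g2"]))
    if (abs(r_g) > 1) {
      message("r_g = ", round(r_g, 4), " clamped to [-1, 1]")
      r_g <- sign(r_g)
    }
    grad_rg <- c(-r_g / (2 * th["g1"]), -r_g / (2 * th["g2"]),
                 1 / sqrt(th["g1"] * th["g2"]), 0, 0, 0)
    se_rg <- delta_se(grad_rg, fit$cov)
  }
  cov_g <- as.numeric(th["gc"] / sqrt(v1 * v2))
  ## gradient in component order (g1, g2, gc, e1, e2, ec)
  grad_cg <- c(-cov_g / (2 * v1), -cov_g / (2 * v2), 1 / sqrt(v1 * v2),
               -cov_g / (2 * v1), -cov_g / (2 * v2), 0)
  se_cg <- delta_se(grad_cg, fit$cov)
  r_e <- as.numeric(th["ec"] / sqrt(th["e1"] * th["e2"]))
  r_e <- max(min(r_e, 1), -1)

  fit0 <- reml_ai_fit(make_null(), theta0[-3], is_var = is_var[-3],
                      cov_bounds = list(c(5L, 3L, 4L)), constrain = constrain,
                      tol = tol, max_iter = max_iter, scale = vp)
  lrt <- max(0, 2 * (fit$loglik - fit0$loglik))
  structure(list(h2_1 = h2_1, h2_2 = h2_2, cov_g = cov_g, r_g = r_g,
                 r_e = r_e, se_r_g = se_rg, se_cov_g = se_cg,
                 lrt_p_rg0 = stats::pchisq(lrt, 1, lower.tail = FALSE),
                 n_overlap = n_overlap, theta = th,
                 loglik_full = fit$loglik, loglik_null_rg0 = fit0$loglik,
                 converged = fit$converged),
            class = "bivariate_estimate")
}

#' @export
print.bivariate_estimate <- function(x, ...) {
  cat(sprintf(
    "bivariate GREML: h2 = %.3f / %.3f, r_g = %.3f (SE %.3f), Cov_g = %.3f, r_e = %.3f, p(r_g=0) = %.3g\n",
    x$h2_1, x$h2_2, x$r_g, x$se_r_g, x$cov_g, x$r_e, x$lrt_p_rg0))
  invisible(x)
}

#' Gene-set partitioned GREML
#'
#' Three-component REML `y ~ N(X beta, A_set s_set + A_noset s_noset +
#' I s_e)` partitioning the genetic variance into contributions of SNPs
#' inside versus outside a gene set. The set component is tested by an LRT
#' against the noset-only reduced model with the 50:50 boundary mixture.
#'
#' @param y a `transformed_measure` or named vector.
#' @param grm_set,grm_noset GRMs built from the set and non-set SNPs over the
#'   same samples.
#' @param constrain constrain variance components to be non-negative. With
#'   `constrain = FALSE` the set component may go negative and the signed
#'   root `z_set = sign(s_set) sqrt(LRT)` is well calibrated under the null,
#'   which the correlated-measure meta-analysis exploits.
#' @param max_iter,tol iteration controls.
#' @return list of class `partitioned_components`: `sigma2_set`,
#'   `sigma2_noset`, `sigma2_e`, `var_set`, `var_noset`, `se_var_set`,
#'   `lrt_p_set`, `z_set`, `n_used`, `converged`.
#' @export
reml_partitioned <- function(y, grm_set, grm_noset, constrain = TRUE,
                             max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(grm_set, "grm"), inherits(grm_noset, "grm"))
  if ((grm_set$n_snps %||% 1L) < 1L || (grm_noset$n_snps %||% 1L) < 1L)
    stop("empty component: each GRM needs at least one SNP", call. = FALSE)
  if (!setequal(grm_set$sample_ids, grm_noset$sample_ids))
    stop("set and noset GRMs must cover identical samples", call. = FALSE)
  y <- align_measure(y, grm_set$sample_ids)
  ids <- names(y)
  if (!setequal(ids, grm_set$sample_ids))
    stop("partitioned REML requires identical id sets for y and the GRMs",
         call. = FALSE)
  n <- length(ids)
  As <- grm_set$values[ids, ids]
  An <- grm_noset$values[ids, ids]
  vp <- stats::var(y)
  backend <- make_dense_backend(y, matrix(1, n, 1), list(As, An, diag(n)))
  fit <- reml_ai_fit(backend, theta0 = c(vp / 4, vp / 4, vp / 2),
                     is_var = rep(TRUE, 3), constrain = constrain,
                     tol = tol, max_iter = max_iter, scale = vp)
  be0 <- make_dense_backend(y, matrix(1, n, 1), list(An, diag(n)))
  fit0 <- reml_ai_fit(be0, theta0 = c(vp / 2, vp / 2), is_var = rep(TRUE, 2),
                      constrain = TRUE, tol = tol, max_iter = max_iter,
                      scale = vp)
  th <- fit$theta
  tot <- th[1] + th[2] + th[3]
  var_set <- th[1] / tot
  grad <- c(tot - th[1], -th[1], -th[1]) / tot^2
  se <- delta_se(grad, fit$cov)
  lrt <- 2 * (fit$loglik - fit0$loglik)
  z_set <- sign(th[1]) * sqrt(max(lrt, 0))
  ## one-sided p of the signed root; equals the 50:50 boundary-mixture p
  ## (0.5 P(chi2_1 > LRT)) whenever the set estimate is non-negative
  structure(list(sigma2_set = th[1], sigma2_noset = th[2], sigma2_e = th[3],
                 var_set = var_set, var_noset = th[2] / tot,
                 se_var_set = se, lrt = max(lrt, 0),
                 lrt_p_set = stats::pnorm(z_set, lower.tail = FALSE),
                 z_set = z_set,
                 loglik_full = fit$loglik, loglik_null = fit0$loglik,
                 n_used = n, converged = fit$converged),
            class = "partitioned_components")
}
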
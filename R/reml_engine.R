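## Average-information REML engine -------------------------------------------
##
## Generic machinery for maximising the restricted log-likelihood of
##   y ~ N(X beta, V(theta)),  V(theta) = sum_k theta_k V_k,
## by average-information (AI) updates with step-halving and scaled-gradient
## (EM-like) fallback when an AI step would leave the feasible region.
## Three backends share the loop:
##   * dense     - arbitrary list of dense V_k (gene-set partitioned fits,
##                 partial-overlap bivariate fits)
##   * diagonal  - single-GRM univariate models rotated to the GRM eigenbasis,
##                 where every V_k is diagonal (O(n) per iteration)
##   * block2    - bivariate models with complete sample overlap rotated to
##                 the shared GRM eigenbasis, where V is block-diagonal with
##                 2x2 blocks (O(n) per iteration)
## The backends return the restricted log-likelihood, the score vector and the
## AI matrix at a given theta; the loop handles constraints and convergence.

reml_constants <- list(rho_max = 1 - 1e-4, var_floor_frac = 1e-6)

## -- dense backend -----------------------------------------------------------

make_dense_backend <- function(y, X, Vlist) {
  n <- length(y); p <- ncol(X); K <- length(Vlist)
  list(
    K = K, n_eff = n - p,
    derivs = function(theta, need_ai = TRUE) {
      V <- matrix(0, n, n)
      for (k in seq_len(K)) V <- V + theta[k] * Vlist[[k]]
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(list(ll = -Inf))
      Vi <- chol2inv(ch)
      ViX <- Vi %*% X
      XtViX <- crossprod(X, ViX)
      chX <- tryCatch(chol(XtViX), error = function(e) NULL)
      if (is.null(chX)) return(list(ll = -Inf))
      beta <- backsolve(chX, forwardsolve(t(chX), crossprod(ViX, y)))
      Py <- Vi %*% y - ViX %*% beta
      ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                    sum(y * Py) + (n - p) * log(2 * pi))
      if (!need_ai) return(list(ll = ll))
      score <- numeric(K)
      U <- vector("list", K)
      for (k in seq_len(K)) {
        u <- Vlist[[k]] %*% Py
        Mk <- crossprod(ViX, Vlist[[k]] %*% ViX)
        trPVk <- sum(Vi * Vlist[[k]]) -
          sum(diag(backsolve(chX, forwardsolve(t(chX), Mk))))
        score[k] <- -0.5 * (trPVk - sum(Py * u))
        U[[k]] <- u
      }
      Pz <- function(z) Vi %*% z - ViX %*%
        backsolve(chX, forwardsolve(t(chX), crossprod(ViX, z)))
      AI <- matrix(0, K, K)
      PU <- lapply(U, Pz)
      for (k in seq_len(K)) for (l in k:K) {
        AI[k, l] <- AI[l, k] <- 0.5 * sum(U[[k]] * PU[[l]])
      }
      list(ll = ll, score = score, AI = AI)
    })
}

## -- diagonal backend (eigen-rotated univariate) -----------------------------

make_diag_backend <- function(ytil, Xtil, wlist) {
  n <- length(ytil); p <- ncol(Xtil); K <- length(wlist)
  list(
    K = K, n_eff = n - p,
    derivs = function(theta, need_ai = TRUE) {
      v <- rep(0, n)
      for (k in seq_len(K)) v <- v + theta[k] * wlist[[k]]
      if (any(v <= 0)) return(list(ll = -Inf))
      ViX <- Xtil / v
      XtViX <- crossprod(Xtil, ViX)
      chX <- tryCatch(chol(XtViX), error = function(e) NULL)
      if (is.null(chX)) return(list(ll = -Inf))
      beta <- backsolve(chX, forwardsolve(t(chX), crossprod(ViX, ytil)))
      Py <- ytil / v - as.vector(ViX %*% beta)
      ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(chX))) +
                    sum(ytil * Py) + (n - p) * log(2 * pi))
      if (!need_ai) return(list(ll = ll))
      score <- numeric(K); U <- vector("list", K)
      for (k in seq_len(K)) {
        w <- wlist[[k]]
        Mk <- crossprod(Xtil, Xtil * (w / v^2))
        trPVk <- sum(w / v) -
          sum(diag(backsolve(chX, forwardsolve(t(chX), Mk))))
        u <- w * Py
        score[k] <- -0.5 * (trPVk - sum(Py * u))
        U[[k]] <- u
      }
      Pz <- function(z) z / v - as.vector(ViX %*%
        backsolve(chX, forwardsolve(t(chX), crossprod(Xtil, z / v))))
      AI <- matrix(0, K, K)
      PU <- lapply(U, Pz)
      for (k in seq_len(K)) for (l in k:K)
        AI[k, l] <- AI[l, k] <- 0.5 * sum(U[[k]] * PU[[l]])
      list(ll = ll, score = score, AI = AI)
    })
}

## -- 2x2 block backend (eigen-rotated complete-overlap bivariate) ------------
## Blocks indexed by GRM eigenvalue d_i:
##   V_i = [[g1 d + e1, gc d + ec], [gc d + ec, g2 d + e2]]
## theta order: (g1, g2, gc, e1, e2, ec).

make_block2_backend <- function(y1t, y2t, u, d) {
  n <- length(d)
  ## derivative blocks as (w11, w22, w12) triples
  Wk <- list(g1 = list(d, 0, 0), g2 = list(0, d, 0), gc = list(0, 0, d),
             e1 = list(1, 0, 0), e2 = list(0, 1, 0), ec = list(0, 0, 1))
  one <- rep(1, n); zero <- rep(0, n)
  expand <- function(w) lapply(w, function(x) if (length(x) == 1)
    (if (x == 0) zero else x * one) else x)
  Wk <- lapply(Wk, expand)
  list(
    K = 6L, n_eff = 2 * n - 2,
    derivs = function(theta, need_ai = TRUE) {
      a <- theta[1] * d + theta[4]
      b <- theta[2] * d + theta[5]
      cc <- theta[3] * d + theta[6]
      det <- a * b - cc^2
      if (any(a <= 0) || any(det <= 0)) return(list(ll = -Inf))
      ia <- b / det; ib <- a / det; ic <- -cc / det   # V^-1 blocks
      bmul <- function(w11, w22, w12, z1, z2)
        list(w11 * z1 + w12 * z2, w12 * z1 + w22 * z2)
      ## X columns (intercept per trait) and V^-1 X
      ViX1 <- bmul(ia, ib, ic, u, zero)
      ViX2 <- bmul(ia, ib, ic, zero, u)
      XtViX <- matrix(c(sum(u * ViX1[[1]]), sum(u * ViX1[[2]]),
                        sum(u * ViX2[[1]]), sum(u * ViX2[[2]])), 2, 2)
      dX <- XtViX[1, 1] * XtViX[2, 2] - XtViX[1, 2] * XtViX[2, 1]
      if (dX <= 0) return(list(ll = -Inf))
      Viy <- bmul(ia, ib, ic, y1t, y2t)
      Xty <- c(sum(u * Viy[[1]]), sum(u * Viy[[2]]))
      beta <- solve(XtViX, Xty)
      Py <- list(Viy[[1]] - beta[1] * ViX1[[1]] - beta[2] * ViX2[[1]],
                 Viy[[2]] - beta[1] * ViX1[[2]] - beta[2] * ViX2[[2]])
      yPy <- sum(y1t * Py[[1]]) + sum(y2t * Py[[2]])
      ll <- -0.5 * (sum(log(det)) + log(dX) + yPy + (2 * n - 2) * log(2 * pi))
      if (!need_ai) return(list(ll = ll))
      ViXs <- list(ViX1, ViX2)
      score <- numeric(6); U <- vector("list", 6)
      for (k in 1:6) {
        w <- Wk[[k]]
        trViW <- sum(ia * w[[1]] + ib * w[[2]] + 2 * ic * w[[3]])
        Mk <- matrix(0, 2, 2)
        for (pp in 1:2) for (qq in 1:2) {
          wz <- bmul(w[[1]], w[[2]], w[[3]], ViXs[[qq]][[1]], ViXs[[qq]][[2]])
          Mk[pp, qq] <- sum(ViXs[[pp]][[1]] * wz[[1]] +
                            ViXs[[pp]][[2]] * wz[[2]])
        }
        trPVk <- trViW - sum(diag(solve(XtViX, Mk)))
        uk <- bmul(w[[1]], w[[2]], w[[3]], Py[[1]], Py[[2]])
        score[k] <- -0.5 * (trPVk -
          (sum(Py[[1]] * uk[[1]]) + sum(Py[[2]] * uk[[2]])))
        U[[k]] <- uk
      }
      Pz <- function(z) {
        Viz <- bmul(ia, ib, ic, z[[1]], z[[2]])
        Xtz <- c(sum(u * Viz[[1]]), sum(u * Viz[[2]]))
        g <- solve(XtViX, Xtz)
        list(Viz[[1]] - g[1] * ViX1[[1]] - g[2] * ViX2[[1]],
             Viz[[2]] - g[1] * ViX1[[2]] - g[2] * ViX2[[2]])
      }
      PU <- lapply(U, Pz)
      AI <- matrix(0, 6, 6)
      for (k in 1:6) for (l in k:6)
        AI[k, l] <- AI[l, k] <- 0.5 *
          (sum(U[[k]][[1]] * PU[[l]][[1]]) + sum(U[[k]][[2]] * PU[[l]][[2]]))
      list(ll = ll, score = score, AI = AI)
    })
}

## -- AI loop -----------------------------------------------------------------
## is_var marks non-negative variance components (when constrain = TRUE);
## cov_bounds is a list of c(cov_index, var_index_1, var_index_2) triples for
## covariance parameters clamped to |c| <= rho_max * sqrt(v1 v2).

reml_ai_fit <- function(backend, theta0, is_var, cov_bounds = list(),
                        constrain = TRUE, tol = 1e-8, max_iter = 100L,
                        scale = 1) {
  floor_val <- reml_constants$var_floor_frac * scale
  project <- function(theta) {
    if (constrain) theta[is_var] <- pmax(theta[is_var], floor_val)
    for (cb in cov_bounds) {
      v1 <- max(theta[cb[2]], floor_val); v2 <- max(theta[cb[3]], floor_val)
      lim <- reml_constants$rho_max * sqrt(v1 * v2)
      theta[cb[1]] <- max(min(theta[cb[1]], lim), -lim)
    }
    theta
  }
  theta <- project(theta0)
  cur <- backend$derivs(theta)
  if (!is.finite(cur$ll)) {
    theta <- project(abs(theta0) + floor_val)
    cur <- backend$derivs(theta)
    if (!is.finite(cur$ll)) stop("REML: infeasible starting values",
                                 call. = FALSE)
  }
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(
      solve(cur$AI + diag(1e-10 * max(diag(cur$AI)) + 1e-300, backend$K),
            cur$score),
      error = function(e) NULL)
    if (is.null(step)) step <- cur$score * (2 * scale / backend$n_eff)
    try_step <- function(step) {
      for (half in 0:25) {
        cand <- project(theta + step / 2^half)
        nxt <- backend$derivs(cand)
        if (is.finite(nxt$ll) && nxt$ll >= cur$ll + 1e-13 * abs(cur$ll))
          return(list(cand = cand, nxt = nxt))
      }
      NULL
    }
    res <- try_step(step)
    if (is.null(res)) {
      ## Jacobi fallback: per-coordinate Newton when the AI matrix is
      ## ill-conditioned (e.g. degenerate duplicated-trait fits)
      dg <- pmax(diag(cur$AI), 1e-12)
      res <- try_step(cur$score / dg)
    }
    if (is.null(res)) {
      ## EM-like scaled-gradient fallback
      res <- try_step(cur$score * (2 * theta^2 + floor_val) / backend$n_eff)
    }
    improved <- !is.null(res)
    if (improved) {
      cand <- res$cand
      nxt <- res$nxt
    }
    if (!improved) {
      ## no ascent direction found: at a (possibly constrained) optimum
      converged <- TRUE
      break
    }
    d_ll <- nxt$ll - cur$ll
    theta <- cand
    cur <- nxt
    if (abs(d_ll) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max_iter > 1)
    warning("REML did not converge after ", max_iter, " iterations")
  AI <- cur$AI
  covmat <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, backend$K, backend$K))
  list(theta = theta, loglik = cur$ll, score = cur$score, AI = AI,
       cov = covmat, converged = converged, iterations = iter)
}

## delta-method SE for a smooth function of theta
delta_se <- function(grad, covmat) {
  v <- as.numeric(t(grad) %*% covmat %*% grad)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

## boundary-mixture p-value for a single variance component on its boundary:
## null distribution 0.5 chi2_0 + 0.5 chi2_1 (reported as 0.5 P(chi2_1 > LRT),
## the GCTA convention, so a zero statistic yields p = 0.5)
boundary_lrt_p <- function(lrt) {
  0.5 * stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
}
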
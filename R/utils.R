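#' @keywords internal
"_PACKAGE"

## Draw n samples from N(0, Sigma) via Cholesky with a PSD-tolerant pivot.
## Rows are samples. Used by the trait and GWAS generators so that all
## randomness flows through R's RNG (seed-reproducible).
rmvn <- function(n, Sigma) {
  p <- ncol(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  L <- ev$vectors %*% diag(sqrt(ev$values), p)
  matrix(stats::rnorm(n * p), n, p) %*% t(L)
}

## Validate a correlation matrix: symmetric, unit diagonal, PSD (to tolerance).
check_corr_matrix <- function(R, name = "correlation matrix", tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop(name, " must be a square matrix", call. = FALSE)
  if (max(abs(R - t(R))) > tol)
    stop(name, " must be symmetric", call. = FALSE)
  if (max(abs(diag(R) - 1)) > tol)
    stop(name, " must have unit diagonal", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6)
    stop(name, " is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  invisible(TRUE)
}

## Standardise dosages column-wise to mean 0, variance 2p(1-p) scale
## (i.e. (x - 2p)/sqrt(2p(1-p))), with missing entries set to 0 so they
## drop out of cross-products. Returns list(W, obs) where obs marks
## non-missing entries.
standardize_dosages <- function(X, freq = NULL) {
  obs <- !is.na(X)
  if (is.null(freq)) freq <- colMeans(X, na.rm = TRUE) / 2
  het <- 2 * freq * (1 - freq)
  W <- sweep(X, 2, 2 * freq, `-`)
  W <- sweep(W, 2, sqrt(het), `/`)
  W[!obs] <- 0
  list(W = W, obs = obs, freq = freq, het = het)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
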
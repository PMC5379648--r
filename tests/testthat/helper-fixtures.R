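## Shared fixture builders: everything is generated in code at test time.

small_panel <- function(n = 60, m = 120, seed = 42, ...) {
  simulate_genotypes(n, m, 0.05, 0.5, seed = seed, ...)
}

## a panel built from an explicit dosage matrix (for hand-computable cases)
panel_from_dosages <- function(X, freq = NULL, chromosome = NULL,
                               position = NULL) {
  n <- nrow(X); m <- ncol(X)
  snps <- data.frame(
    snp_id = sprintf("s%03d", seq_len(m)),
    chromosome = chromosome %||% rep(1L, m),
    position = position %||% seq(1e4, by = 1e4, length.out = m),
    allele_ref = "A", allele_alt = "G",
    allele_freq = freq %||% (colMeans(X, na.rm = TRUE) / 2),
    stringsAsFactors = FALSE)
  colnames(X) <- snps$snp_id
  ids <- sprintf("i%03d", seq_len(n))
  rownames(X) <- ids
  structure(list(sample_ids = ids, snps = snps, dosages = X),
            class = "genotype_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## brute-force GRM oracle: element-by-element double loop with pairwise
## complete SNPs and in-sample frequencies (independent of the kernel code)
grm_oracle <- function(X) {
  n <- nrow(X); m <- ncol(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- which(p > 0 & p < 1)          # monomorphic SNPs carry no signal
  out <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0; cc <- 0L
    for (i in poly) {
      if (is.na(X[j, i]) || is.na(X[k, i])) next
      s <- s + (X[j, i] - 2 * p[i]) * (X[k, i] - 2 * p[i]) /
        (2 * p[i] * (1 - p[i]))
      cc <- cc + 1L
    }
    out[j, k] <- s / max(cc, 1L)
    cnt[j, k] <- cc
  }
  list(values = out, counts = cnt)
}

## dense restricted log-likelihood oracle (independent of the REML engine)
reml_ll_oracle <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus +
                     t(r) %*% Vi %*% r + (n - p) * log(2 * pi)))
}

## a simple two-measure transformed fixture from a simulated cohort
quick_measures <- function(panel, spec) {
  pheno <- simulate_longitudinal_traits(panel, spec)
  labs <- attr(pheno, "labels")
  ms <- lapply(seq_along(labs), function(i) {
    tr <- spec$trait_of[i]
    transform_measure(pheno, tr, spec$ages[i])
  })
  names(ms) <- labs
  ms
}
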
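#' OLS residualisation of a trait measure on standard covariates
#'
#' Ordinary-least-squares residuals of the raw score on an intercept, sex,
#' exact age and the two ancestry-informative principal components. Rows with
#' any missing covariate or score are dropped (with a message).
#'
#' @param table a `phenotype_table` (long format).
#' @param trait trait label to select.
#' @param age_band age band (years) to select.
#' @param covariates covariate columns, default `c("sex","age","pc1","pc2")`.
#' @return Named numeric vector of residuals (names = individual ids).
#' @export
residualize <- function(table, trait, age_band,
                        covariates = c("sex", "age", "pc1", "pc2")) {
  rows <- table[table$trait == trait & table$age_band == age_band, ,
                drop = FALSE]
  if (!nrow(rows)) stop("no rows for ", trait, " at age ", age_band,
                        call. = FALSE)
  cc <- stats::complete.cases(rows[, c("score", covariates)])
  if (any(!cc))
    message(sum(!cc), " incomplete case(s) dropped for ", trait, "_", age_band)
  rows <- rows[cc, , drop = FALSE]
  if (nrow(rows) < 10) stop("fewer than 10 complete cases", call. = FALSE)
  X <- cbind(1, as.matrix(rows[, covariates, drop = FALSE]))
  colnames(X) <- c("(intercept)", covariates)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    bad <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qr_X, rows$score)
  stats::setNames(as.numeric(res), rows$iid)
}

#' Rank-based inverse-normal transformation (Blom offsets)
#'
#' Maps values to `qnorm((rank - 3/8) / (n + 1/4))` using average ranks for
#' ties. Integer questionnaire scores produce heavy ties, so the average-rank
#' convention is load-bearing: tied observations receive identical
#' transformed values.
#'
#' @param values numeric vector (n >= 3, not all equal).
#' @param ids optional identifiers (defaults to `names(values)`).
#' @param provenance optional list describing the measure's origin.
#' @return A `transformed_measure`: list with `individual_ids`, `values`
#'   (mean ~0, variance ~1) and `provenance`.
#' @export
rank_inverse_normal <- function(values, ids = names(values),
                                provenance = list()) {
  if (length(values) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate input: all values identical", call. = FALSE)
  n <- length(values)
  r <- rank(values, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  structure(list(individual_ids = ids %||% as.character(seq_len(n)),
                 values = z, provenance = provenance),
            class = "transformed_measure")
}

#' Residualise and rank-transform one trait measure
#'
#' Convenience composition of [residualize()] and [rank_inverse_normal()].
#' @inheritParams residualize
#' @return a `transformed_measure` labelled `<trait>_<age_band>`.
#' @export
transform_measure <- function(table, trait, age_band,
                              covariates = c("sex", "age", "pc1", "pc2")) {
  res <- residualize(table, trait, age_band, covariates)
  rank_inverse_normal(res, ids = names(res),
                      provenance = list(trait = trait, age_band = age_band,
                                        covariates = covariates,
                                        label = paste0(trait, "_", age_band)))
}

#' Write a transformed measure to TSV (iid, value)
#' @param measure a `transformed_measure`.
#' @param path output file.
#' @export
write_measure <- function(measure, path) {
  utils::write.table(data.frame(iid = measure$individual_ids,
                                value = measure$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transformed measure from TSV (iid, value)
#' @param path input file.
#' @param provenance optional provenance list.
#' @export
read_measure <- function(path, provenance = list()) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  structure(list(individual_ids = as.character(x$iid), values = x$value,
                 provenance = provenance),
            class = "transformed_measure")
}

#' Correlation matrix across measures
#'
#' Pairwise-complete Pearson or Spearman correlations across a list of
#' measures (`transformed_measure` objects or plain named vectors), aligned
#' on individual ids.
#'
#' @param measures named list of measures.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `correlation_matrix`: list with `labels`, `values`, `method`.
#' @export
correlation_matrix <- function(measures, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  as_named <- function(m) {
    if (inherits(m, "transformed_measure"))
      stats::setNames(m$values, m$individual_ids)
    else if (!is.null(names(m))) m
    else stop("measures must be transformed_measure objects or named vectors",
              call. = FALSE)
  }
  vecs <- lapply(measures, as_named)
  labels <- names(measures) %||% paste0("m", seq_along(measures))
  k <- length(vecs)
  R <- diag(1, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j >= i) next
    common <- intersect(names(vecs[[i]]), names(vecs[[j]]))
    if (length(common) < 3)
      stop("fewer than 3 overlapping ids for pair ", labels[i], "/",
           labels[j], call. = FALSE)
    xi <- vecs[[i]][common]; xj <- vecs[[j]][common]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0)
      stop("undefined correlation (zero variance) for pair ", labels[i], "/",
           labels[j], call. = FALSE)
    R[i, j] <- R[j, i] <- stats::cor(xi, xj, method = method)
  }
  dimnames(R) <- list(labels, labels)
  structure(list(labels = labels, values = R, method = method),
            class = "correlation_matrix")
}

#' Effective number of independent measures and experiment-wise error rate
#'
#' The effective number of tests follows the eigenvalue-spectrum formula
#' `Meff = 1 + (M - 1) (1 - var(lambda) / M)` (rounded to the nearest
#' integer), and the experiment-wise error rate is the Sidak step
#' `alpha_e = 1 - (1 - alpha_family)^(1 / Meff)`. With five independent
#' measures and a family alpha of 0.05 this gives 0.0102.
#'
#' @param corr a `correlation_matrix` (or square correlation matrix).
#' @param alpha_family family-wise alpha in (0,1), default 0.05.
#' @param exclude optional labels excluded before the eigen-decomposition
#'   (e.g. measures with near-zero genetic variance, at the caller's choice).
#' @return list with `m_observed`, `m_effective`, `alpha_family`,
#'   `alpha_experimentwise`.
#' @export
effective_tests <- function(corr, alpha_family = 0.05, exclude = NULL) {
  if (alpha_family <= 0 || alpha_family >= 1)
    stop("alpha_family must lie in (0,1)", call. = FALSE)
  R <- if (inherits(corr, "correlation_matrix")) corr$values else corr
  if (!is.null(exclude)) {
    keep <- setdiff(colnames(R), exclude)
    R <- R[keep, keep, drop = FALSE]
  }
  check_corr_matrix(R, "correlation matrix")
  M <- nrow(R)
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  meff <- if (M == 1) 1 else 1 + (M - 1) * (1 - stats::var(lam) / M)
  meff <- max(1L, min(M, as.integer(round(meff))))
  list(m_observed = M, m_effective = meff, alpha_family = alpha_family,
       alpha_experimentwise = 1 - (1 - alpha_family)^(1 / meff))
}
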
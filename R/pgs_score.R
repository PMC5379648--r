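#' LD clumping of summary statistics against a genotype panel
#'
#' Greedy p-value-ordered clumping: repeatedly take the unclaimed SNP with
#' the smallest p-value as an index SNP and remove all unclaimed SNPs within
#' `+/- window` bp on the same chromosome whose squared dosage correlation
#' with the index exceeds `r2_threshold`. Ties in p are broken by
#' (chromosome, position). Duplicate SNP ids keep the smaller p; summary
#' SNPs absent from the panel are dropped with a logged count.
#'
#' @param sumstats a `summary_stats` data.frame.
#' @param panel a `genotype_panel` providing the LD reference.
#' @param r2_threshold squared-correlation threshold (default 0.25).
#' @param window one-sided window in bp (default 500 kb).
#' @return character vector of retained snp ids.
#' @export
clump <- function(sumstats, panel, r2_threshold = 0.25, window = 5e5) {
  ss <- as.data.frame(sumstats)
  dup <- duplicated(ss$snp_id[order(ss$p_value)])
  if (any(dup)) {
    ss <- ss[order(ss$p_value), ][!dup, ]
    message(sum(dup), " duplicate SNP id(s) removed (smaller p kept)")
  }
  absent <- !(ss$snp_id %in% panel$snps$snp_id)
  if (any(absent)) {
    message(sum(absent), " summary SNP(s) absent from panel dropped")
    ss <- ss[!absent, , drop = FALSE]
  }
  info <- panel$snps[match(ss$snp_id, panel$snps$snp_id), ]
  ord <- order(ss$p_value, info$chromosome, info$position)
  ss <- ss[ord, ]; info <- info[ord, ]
  X <- panel$dosages[, ss$snp_id, drop = FALSE]
  claimed <- rep(FALSE, nrow(ss))
  keep <- character(0)
  for (i in seq_len(nrow(ss))) {
    if (claimed[i]) next
    keep <- c(keep, ss$snp_id[i])
    claimed[i] <- TRUE
    near <- which(!claimed & info$chromosome == info$chromosome[i] &
                  abs(info$position - info$position[i]) <= window)
    if (length(near)) {
      r <- suppressWarnings(stats::cor(X[, i], X[, near, drop = FALSE],
                                       use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      claimed[near[r[1, ]^2 > r2_threshold]] <- TRUE
    }
  }
  keep
}

#' Build Z-standardised polygenic scores over a threshold grid
#'
#' Per threshold `P_T`, the score is the sum over clumped SNPs with
#' `p <= P_T` of the dosage aligned to the effect allele times the reported
#' effect (log-odds). A missing dosage contributes its expectation
#' `2 * freq * effect`; when the effect allele is the panel's reference
#' allele the dosage is complemented (`2 - x`), which leaves the score
#' invariant under allele-label flips. Scores are Z-standardised across
#' individuals per threshold.
#'
#' @param panel a `genotype_panel`.
#' @param sumstats a `summary_stats` data.frame.
#' @param clumped_ids SNPs surviving [clump()].
#' @param thresholds p-value thresholds in (0.001, 1], default
#'   `c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1)`.
#' @return An object of class `polygenic_scores`: list with `sample_ids`,
#'   `thresholds`, `scores` (individuals x thresholds, standardised),
#'   `n_snps` (SNPs entering each column) and `usable` (flags columns with
#'   at least one SNP and nonzero variance).
#' @export
build_scores <- function(panel, sumstats, clumped_ids,
                         thresholds = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4,
                                        0.5, 1)) {
  if (any(thresholds <= 0.001 | thresholds > 1))
    stop("thresholds must lie in (0.001, 1]", call. = FALSE)
  ss <- as.data.frame(sumstats)
  ss <- ss[match(clumped_ids, ss$snp_id), , drop = FALSE]
  info <- panel$snps[match(clumped_ids, panel$snps$snp_id), ]
  X <- panel$dosages[, clumped_ids, drop = FALSE]
  storage.mode(X) <- "double"
  ## align to the effect allele
  flip <- ss$allele_effect == info$allele_ref &
          ss$allele_other == info$allele_alt
  ok <- flip | (ss$allele_effect == info$allele_alt &
                ss$allele_other == info$allele_ref)
  if (any(!ok)) {
    message(sum(!ok), " SNP(s) with unresolvable alleles dropped")
    ss <- ss[ok, ]; info <- info[ok, ]; X <- X[, ok, drop = FALSE]
    flip <- flip[ok]
  }
  if (any(flip)) X[, flip] <- 2 - X[, flip, drop = FALSE]
  freq_eff <- ifelse(flip, 1 - info$allele_freq, info$allele_freq)
  ## missing dosages at their expectation
  for (j in which(colSums(is.na(X)) > 0))
    X[is.na(X[, j]), j] <- 2 * freq_eff[j]

  n <- nrow(X)
  scores <- matrix(0, n, length(thresholds))
  n_snps <- integer(length(thresholds))
  usable <- logical(length(thresholds))
  for (t in seq_along(thresholds)) {
    sel <- ss$p_value <= thresholds[t]
    n_snps[t] <- sum(sel)
    if (!n_snps[t]) {
      usable[t] <- FALSE
      next
    }
    s <- as.vector(X[, sel, drop = FALSE] %*% ss$effect[sel])
    if (stats::sd(s) == 0) {
      usable[t] <- FALSE
      scores[, t] <- 0
    } else {
      scores[, t] <- (s - mean(s)) / stats::sd(s)
      usable[t] <- TRUE
    }
  }
  colnames(scores) <- paste0("PT_", thresholds)
  structure(list(sample_ids = panel$sample_ids, thresholds = thresholds,
                 scores = scores, n_snps = n_snps, usable = usable),
            class = "polygenic_scores")
}

#' Write a polygenic score set to TSV (iid, one column per threshold)
#' @param scores a `polygenic_scores` object.
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  out <- data.frame(iid = scores$sample_ids, scores$scores,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-sectional PGS-trait association by ordinary least squares
#'
#' Per usable threshold, regresses the (rank-transformed) trait on the
#' Z-standardised score and reports the slope, its standard error and
#' p-value, and the adjusted regression R^2.
#'
#' @param scores a `polygenic_scores` object.
#' @param y a `transformed_measure` or named numeric vector.
#' @return data.frame with one row per threshold: `threshold`, `n_snps`,
#'   `n`, `beta`, `se`, `p`, `adj_r2` (NA rows for unusable thresholds).
#' @export
assoc_cross_sectional <- function(scores, y) {
  if (inherits(y, "transformed_measure"))
    y <- stats::setNames(y$values, y$individual_ids)
  common <- intersect(scores$sample_ids, names(y))
  if (length(common) < 30)
    stop("id overlap between scores and trait below 30", call. = FALSE)
  idx <- match(common, scores$sample_ids)
  yy <- y[common]
  out <- lapply(seq_along(scores$thresholds), function(t) {
    row <- data.frame(threshold = scores$thresholds[t],
                      n_snps = scores$n_snps[t], n = length(common),
                      beta = NA_real_, se = NA_real_, p = NA_real_,
                      adj_r2 = NA_real_)
    if (!scores$usable[t]) {
      message("threshold ", scores$thresholds[t], " unusable; skipped")
      return(row)
    }
    fit <- summary(stats::lm(yy ~ scores$scores[idx, t]))
    row$beta <- fit$coefficients[2, 1]
    row$se <- fit$coefficients[2, 2]
    row$p <- fit$coefficients[2, 4]
    row$adj_r2 <- fit$adj.r.squared
    row
  })
  do.call(rbind, out)
}
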
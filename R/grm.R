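#' Compute a genetic relationship matrix (GRM)
#'
#' Entry (j,k) is the average standardised-genotype cross-product
#' `(1/M_jk) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))` over the
#' SNPs non-missing in both individuals, with `p_i` the in-sample alternate
#' allele frequency computed from non-missing dosages. Missing dosages are
#' excluded pairwise and per-pair SNP counts are retained; monomorphic SNPs
#' are skipped with a warning.
#'
#' @param panel a `genotype_panel`.
#' @param snp_subset optional character vector of SNP ids to use.
#' @return An object of class `grm`: list with `sample_ids`, `values`
#'   (symmetric n x n matrix) and `pair_snp_counts` (integer matrix).
#' @export
compute_grm <- function(panel, snp_subset = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$dosages
  if (!is.null(snp_subset)) {
    miss <- setdiff(snp_subset, colnames(X))
    if (length(miss))
      stop("subset SNPs absent from panel: ", paste(utils::head(miss, 3),
           collapse = ", "), call. = FALSE)
    X <- X[, snp_subset, drop = FALSE]
  }
  freq <- colMeans(X, na.rm = TRUE) / 2
  mono <- freq <= 0 | freq >= 1 | is.na(freq)
  if (all(mono))
    stop("all SNPs monomorphic: empty GRM", call. = FALSE)
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) skipped")
    X <- X[, !mono, drop = FALSE]
    freq <- freq[!mono]
  }
  st <- standardize_dosages(X, freq)
  vals <- tcrossprod(st$W)
  counts <- tcrossprod(st$obs * 1)
  vals <- vals / pmax(counts, 1)
  storage.mode(counts) <- "integer"
  dimnames(vals) <- dimnames(counts) <- list(panel$sample_ids, panel$sample_ids)
  structure(list(sample_ids = panel$sample_ids, values = vals,
                 pair_snp_counts = counts, n_snps = ncol(X)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$sample_ids), "individuals,",
      x$n_snps %||% NA, "SNPs; mean diagonal",
      round(mean(diag(x$values)), 4), "\n")
  invisible(x)
}

#' Greedily prune related individuals from a GRM
#'
#' While any off-diagonal relationship exceeds `cutoff`, the individual
#' participating in the most offending pairs is removed (ties broken by
#' taking the lexicographically smallest sample id). The returned set has no
#' remaining pairwise relationship above the cutoff.
#'
#' @param grm a `grm`.
#' @param cutoff relationship threshold (> 0), e.g. 0.025.
#' @return Character vector of retained sample ids (in original order).
#' @export
prune_related <- function(grm, cutoff = 0.025) {
  stopifnot(inherits(grm, "grm"), cutoff > 0)
  A <- grm$values
  diag(A) <- 0
  keep <- rep(TRUE, nrow(A))
  ids <- grm$sample_ids
  repeat {
    off <- A[keep, keep, drop = FALSE] > cutoff
    deg <- rowSums(off)
    if (!any(deg > 0)) break
    sub_ids <- ids[keep]
    worst <- sub_ids[deg == max(deg)]
    drop_id <- sort(worst)[1]
    keep[match(drop_id, ids)] <- FALSE
  }
  ids[keep]
}

#' Partition a panel's SNPs by a gene set with flanks
#'
#' A SNP is in-set iff its position lies within `[start - flank, end + flank]`
#' (1-based, inclusive) of any listed gene on the same chromosome; the
#' remainder form the noset list. The two lists are disjoint and jointly
#' exhaust the panel.
#'
#' @param panel a `genotype_panel`.
#' @param annotation a `gene_annotation`.
#' @param gene_ids genes defining the set (must exist in the annotation).
#' @param flank flank size in bp (>= 0), default 50 kb.
#' @return list with `set_snp_ids`, `noset_snp_ids`, `provenance`.
#' @export
partition_by_geneset <- function(panel, annotation, gene_ids, flank = 5e4) {
  stopifnot(flank >= 0)
  miss <- setdiff(gene_ids, annotation$gene_id)
  if (length(miss))
    stop("unknown gene id(s): ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  genes <- annotation[annotation$gene_id %in% gene_ids, , drop = FALSE]
  snps <- panel$snps
  in_set <- rep(FALSE, nrow(snps))
  for (i in seq_len(nrow(genes))) {
    in_set <- in_set | (snps$chromosome == genes$chromosome[i] &
                        snps$position >= genes$start[i] - flank &
                        snps$position <= genes$end[i] + flank)
  }
  list(set_snp_ids = snps$snp_id[in_set],
       noset_snp_ids = snps$snp_id[!in_set],
       provenance = list(gene_ids = gene_ids, flank = flank))
}

#' Write a gene annotation as BED (0-based, half-open)
#' @param annotation a `gene_annotation` (1-based inclusive internally).
#' @param path output file.
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- data.frame(chrom = paste0("chr", annotation$chromosome),
                    start = annotation$start - 1L, end = annotation$end,
                    name = annotation$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of genes (converted to 1-based inclusive intervals)
#' @param path BED file (chrom, start, end, name).
#' @export
read_annotation_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = bed[[4]],
                    chromosome = as.integer(sub("^chr", "", bed[[1]])),
                    start = bed[[2]] + 1L, end = bed[[3]],
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}
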
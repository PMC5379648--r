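#' Simulate a genotype panel under Hardy-Weinberg equilibrium
#'
#' Generates an individuals-by-SNPs dosage matrix emulating a post-QC
#' genotyping chip: biallelic autosomal SNPs with allele frequencies drawn
#' uniformly from `[maf_low, maf_high]`, dosages drawn as two independent
#' Bernoulli allele draws per individual (Binomial(2, p)), laid out on 22
#' chromosomes with strictly increasing positions.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param n_snps number of SNPs (>= 2, except via `n_snps = 1` for degenerate
#'   test cases).
#' @param maf_low,maf_high bounds for the generating allele frequency,
#'   `0.01 <= maf_low < maf_high <= 0.5`.
#' @param seed integer seed; the panel is bit-identical for a given seed.
#' @param missing_rate proportion of dosages set missing (`NA`), default 0.
#' @param chr_length chromosome length in base pairs used for uniform
#'   position placement (default 100 Mb).
#'
#' @return An object of class `genotype_panel`: a list with `sample_ids`,
#'   `snps` (data.frame: `snp_id`, `chromosome`, `position`, `allele_ref`,
#'   `allele_alt`, `allele_freq`) and `dosages` (integer matrix, individuals
#'   x SNPs, counting the alternate allele, `NA` = missing).
#' @export
simulate_genotypes <- function(n_individuals, n_snps, maf_low = 0.05,
                               maf_high = 0.5, seed = 1, missing_rate = 0,
                               chr_length = 1e8) {
  if (!(maf_low >= 0.01 && maf_low < maf_high && maf_high <= 0.5))
    stop("invalid MAF bounds: need 0.01 <= maf_low < maf_high <= 0.5",
         call. = FALSE)
  if (n_individuals < 2 || n_snps < 1)
    stop("need n_individuals >= 2 and n_snps >= 1", call. = FALSE)
  set.seed(seed)

  maf <- stats::runif(n_snps, maf_low, maf_high)
  chrom <- sort(rep_len(1:22, n_snps))
  pos <- integer(n_snps)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(chr_length, length(idx)))
  }
  snps <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(n_snps)),
    chromosome = chrom, position = pos,
    allele_ref = "A", allele_alt = "G",
    allele_freq = maf, stringsAsFactors = FALSE)

  dos <- matrix(stats::rbinom(n_individuals * n_snps, 2L,
                              rep(maf, each = n_individuals)),
                n_individuals, n_snps)
  if (missing_rate > 0)
    dos[stats::runif(length(dos)) < missing_rate] <- NA_integer_
  colnames(dos) <- snps$snp_id
  ids <- sprintf("ind%05d", seq_len(n_individuals))
  rownames(dos) <- ids

  structure(list(sample_ids = ids, snps = snps, dosages = dos),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$sample_ids), "individuals x",
      nrow(x$snps), "SNPs on", length(unique(x$snps$chromosome)),
      "chromosomes\n")
  invisible(x)
}

#' Simulate a gene annotation over a panel's chromosomes
#'
#' Places `n_genes` non-overlapping genes with exponentially distributed
#' lengths (mean `mean_length`) on the panel's chromosomes, round-robin.
#' Intervals are 1-based and inclusive.
#'
#' @param panel a `genotype_panel`.
#' @param n_genes number of genes (>= 1).
#' @param mean_length mean gene length in base pairs.
#' @param seed integer seed.
#' @param chr_length chromosome length (must match the panel's layout).
#' @return A `gene_annotation`: data.frame with `gene_id`, `chromosome`,
#'   `start`, `end` (1-based, inclusive, `start <= end`).
#' @export
simulate_annotation <- function(panel, n_genes, mean_length = 2e4, seed = 1,
                                chr_length = 1e8) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  set.seed(seed)
  chroms <- sort(unique(panel$snps$chromosome))
  chrom <- rep_len(chroms, n_genes)
  lens <- pmax(0L, as.integer(round(stats::rexp(n_genes, 1 / max(mean_length, 1e-9)))))
  start <- integer(n_genes); end <- integer(n_genes)
  for (ch in chroms) {
    idx <- which(chrom == ch)
    need <- sum(lens[idx] + 1)
    if (need > chr_length)
      stop("chromosome ", ch, " too short to place ", length(idx),
           " genes without overlap", call. = FALSE)
    # random non-overlapping placement: distribute the slack uniformly
    slack <- chr_length - need
    gaps <- sort(sample.int(slack + 1, length(idx))) - 1L
    off <- cumsum(c(0L, utils::head(lens[idx] + 1L, -1L)))
    start[idx] <- 1L + gaps + off
    end[idx] <- start[idx] + lens[idx]
  }
  ann <- data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
                    chromosome = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}
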
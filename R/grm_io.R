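#' Write a GRM in GCTA binary format
#'
#' Three files are produced: `<prefix>.grm.bin` (lower triangle of the
#' relationship matrix, diagonal included, as 4-byte little-endian floats),
#' `<prefix>.grm.N.bin` (per-pair non-missing SNP counts, same layout, as
#' floats) and `<prefix>.grm.id` (two-column text: family id, individual id).
#'
#' @param grm a `grm`.
#' @param prefix path prefix for the three files.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$sample_ids)
  lt <- which(lower.tri(grm$values, diag = TRUE))
  ## lower triangle in row order (GCTA stores pair (j,k<=j) sequentially)
  ord <- order(row(grm$values)[lt], col(grm$values)[lt])
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(grm$values[lt][ord]), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(grm$pair_snp_counts[lt][ord]), con, size = 4,
           endian = "little")
  close(con)
  utils::write.table(data.frame(grm$sample_ids, grm$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM from GCTA binary format
#'
#' @param prefix path prefix; `<prefix>.grm.bin`, `<prefix>.grm.N.bin` and
#'   `<prefix>.grm.id` must all exist. Ids are taken in file order.
#' @return a `grm` (float32 precision).
#' @export
read_grm <- function(prefix) {
  idf <- paste0(prefix, ".grm.id")
  binf <- paste0(prefix, ".grm.bin")
  nf <- paste0(prefix, ".grm.N.bin")
  for (f in c(idf, binf, nf))
    if (!file.exists(f)) stop("missing GRM component file: ", f, call. = FALSE)
  ids <- utils::read.table(idf, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  m_expect <- n * (n + 1) / 2
  read_tri <- function(f) {
    sz <- file.info(f)$size
    if (sz != 4 * m_expect)
      stop("GRM format error in ", f, ": expected ", m_expect,
           " float32 elements (n(n+1)/2 for n = ", n, "), found ", sz / 4,
           call. = FALSE)
    con <- file(f, "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = m_expect, size = 4, endian = "little")
  }
  vals_tri <- read_tri(binf)
  cnt_tri <- read_tri(nf)
  V <- matrix(0, n, n)
  Nm <- matrix(0, n, n)
  k <- 1L
  for (j in seq_len(n)) {
    V[j, 1:j] <- vals_tri[k:(k + j - 1L)]
    Nm[j, 1:j] <- cnt_tri[k:(k + j - 1L)]
    k <- k + j
  }
  V[upper.tri(V)] <- t(V)[upper.tri(V)]
  Nm[upper.tri(Nm)] <- t(Nm)[upper.tri(Nm)]
  storage.mode(Nm) <- "integer"
  dimnames(V) <- dimnames(Nm) <- list(ids, ids)
  structure(list(sample_ids = ids, values = V, pair_snp_counts = Nm),
            class = "grm")
}

#' Write a genotype panel as PLINK bed/bim/fam
#'
#' SNP-major 2-bit bed encoding (magic bytes 0x6c 0x1b 0x01). The counted
#' allele A1 is the panel's alternate allele, so dosage 2 encodes homozygous
#' A1 (bits 00), 1 the heterozygote (10), 0 homozygous A2 (11), and missing
#' dosages map to 01.
#'
#' @param panel a `genotype_panel`.
#' @param prefix path prefix for the `.bed`, `.bim`, `.fam` files.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$dosages
  n <- nrow(X); m <- ncol(X)
  codes <- c(`2` = 0L, NA_ = 1L, `1` = 2L, `0` = 3L)
  enc <- matrix(3L, n, m)
  enc[!is.na(X) & X == 2L] <- 0L
  enc[!is.na(X) & X == 1L] <- 2L
  enc[is.na(X)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4 - n
  out <- raw(3 + bytes_per_snp * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  shift <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    g <- c(enc[, j], integer(pad))
    gm <- matrix(g, nrow = 4)
    byte_vals <- colSums(gm * shift)
    out[3 + (j - 1) * bytes_per_snp + seq_len(bytes_per_snp)] <-
      as.raw(byte_vals)
  }
  writeBin(out, paste0(prefix, ".bed"))
  bim <- data.frame(panel$snps$chromosome, panel$snps$snp_id, 0,
                    panel$snps$position, panel$snps$allele_alt,
                    panel$snps$allele_ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(panel$sample_ids, panel$sample_ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam fileset into a genotype panel
#'
#' @param prefix path prefix; expects the SNP-major 2-bit bed dialect.
#' @return a `genotype_panel` with dosages counting the bim A1 allele.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE)
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = file.info(paste0(prefix, ".bed"))$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file", call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported", call. = FALSE)
  bytes_per_snp <- ceiling(n / 4)
  if (length(raw) - 3 != bytes_per_snp * m)
    stop("bed size mismatch: expected ", bytes_per_snp * m,
         " genotype bytes, found ", length(raw) - 3, call. = FALSE)
  body <- as.integer(raw[-(1:3)])
  ## decode all 4 two-bit fields per byte
  q <- matrix(0L, 4, length(body))
  rem <- body
  for (b in 1:4) {
    q[b, ] <- rem %% 4L
    rem <- rem %/% 4L
  }
  decode <- c(2L, NA_integer_, 1L, 0L)   # 00, 01, 10, 11
  X <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    cols <- (j - 1) * bytes_per_snp + seq_len(bytes_per_snp)
    g <- as.vector(q[, cols])[seq_len(n)]
    X[, j] <- decode[g + 1L]
  }
  colnames(X) <- bim[[2]]
  rownames(X) <- fam[[2]]
  snps <- data.frame(snp_id = bim[[2]], chromosome = as.integer(bim[[1]]),
                     position = bim[[4]], allele_ref = bim[[6]],
                     allele_alt = bim[[5]],
                     allele_freq = colMeans(X, na.rm = TRUE) / 2,
                     stringsAsFactors = FALSE)
  structure(list(sample_ids = fam[[2]], snps = snps, dosages = X),
            class = "genotype_panel")
}
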
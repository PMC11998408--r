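#' Construct a genotype matrix container
#'
#' @param dosage Integer/numeric samples x SNPs matrix with values 0/1/2
#'   (copies of the counted allele, normally the minor allele) or `NA`.
#' @param samples Character sample ids (length `nrow(dosage)`).
#' @param snps `data.frame` with columns `chr`, `id`, `pos` (1-based bp),
#'   `a1` (counted allele), `a2`; positions strictly increasing within
#'   chromosome.
#' @return Object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(dosage, samples, snps) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == length(samples),
            ncol(dosage) == nrow(snps),
            all(c("chr", "id", "pos", "a1", "a2") %in% names(snps)))
  if (any(!is.na(dosage) & !(dosage %in% 0:2))) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  for (ch in unique(snps$chr)) {
    p <- snps$pos[snps$chr == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on chromosome ", ch,
           call. = FALSE)
    }
  }
  dimnames(dosage) <- list(samples, snps$id)
  structure(list(dosage = dosage, samples = as.character(samples),
                 snps = as.data.frame(snps, stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", length(x$samples), "samples x", nrow(x$snps),
      "SNPs on", length(unique(x$snps$chr)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosage))
  if (miss > 0) cat("  missing rate:", signif(miss, 3), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @param samples,snps Logical/integer/character selectors (default keep all).
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(g$samples) else {
    if (is.character(samples)) match(samples, g$samples) else samples
  }
  vi <- if (is.null(snps)) seq_len(nrow(g$snps)) else {
    if (is.character(snps)) match(snps, g$snps$id) else snps
  }
  genotype_matrix(g$dosage[si, vi, drop = FALSE], g$samples[si],
                  g$snps[vi, , drop = FALSE])
}

#' Allele frequency and MAF of each SNP
#'
#' @param g A [genotype_matrix()].
#' @return `data.frame` with `id`, `freq` (frequency of the counted allele),
#'   `maf`, `call_rate`.
#' @export
snp_stats <- function(g) {
  f <- colMeans(g$dosage, na.rm = TRUE) / 2
  data.frame(id = g$snps$id, freq = f, maf = pmin(f, 1 - f),
             call_rate = colMeans(!is.na(g$dosage)), row.names = NULL)
}

# decode table: byte value (0..255) -> 4 dosages, PLINK .bed 2-bit codes
# 00 = 2 copies of A1, 01 = missing, 10 = het, 11 = 0 copies of A1
plink_decode_table <- function() {
  code_to_dosage <- c(2L, NA_integer_, 1L, 0L)
  t(vapply(0:255, function(b) {
    code_to_dosage[bitwAnd(bitwShiftR(b, 2L * (0:3)), 3L) + 1L]
  }, integer(4L)))
}

#' Read PLINK bed/bim/fam genotypes
#'
#' Parses the binary SNP-major `.bed` file directly (magic bytes `6c 1b 01`),
#' with `.bim` supplying SNP metadata and `.fam` the sample ids. Dosages
#' count copies of the A1 allele (PLINK's default minor allele).
#' Chromosome names are taken verbatim.
#'
#' @param prefix Path prefix (without extension).
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  n <- nrow(fam); m <- nrow(bim)
  bpv <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + as.double(bpv) * m)
  if (length(raw) < 3L + bpv * m ||
      raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic bytes): ", prefix, ".bed",
         call. = FALSE)
  }
  if (raw[3L] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported", call. = FALSE)
  }
  tab <- plink_decode_table()
  bytes <- as.integer(raw[-(1:3)])
  lanes <- tab[bytes + 1L, , drop = FALSE]        # (bpv*m) x 4
  dos <- matrix(as.vector(t(lanes)), nrow = 4L * bpv)[seq_len(n), ,
                                                      drop = FALSE]
  snps <- bim[, c("chr", "id", "pos", "a1", "a2")]
  snps$chr <- as.character(snps$chr)
  genotype_matrix(dos, as.character(fam$V2), snps)
}

#' Write PLINK bed/bim/fam files
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @return Invisibly, `prefix`.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$samples); m <- nrow(g$snps)
  fam <- data.frame(g$samples, g$samples, 0L, 0L, 0L, -9L)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(g$snps$chr, g$snps$id, 0L, g$snps$pos, g$snps$a1,
                    g$snps$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, nrow = n, ncol = m)
  code[is.na(g$dosage)] <- 1L
  code[!is.na(g$dosage) & g$dosage == 1] <- 2L
  code[!is.na(g$dosage) & g$dosage == 2] <- 0L
  bpv <- ceiling(n / 4)
  pad <- 4L * bpv - n
  if (pad > 0L) code <- rbind(code, matrix(0L, pad, m))
  shifts <- 2L * (0:3)
  lane <- function(j) code[seq(j, nrow(code), by = 4L), , drop = FALSE]
  bytes <- lane(1L) + bitwShiftL(lane(2L), 2L) + bitwShiftL(lane(3L), 4L) +
    bitwShiftL(lane(4L), 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read biallelic genotypes from a VCF
#'
#' Uses `vcfR` to parse the VCF and the GT field. Multi-allelic rows are
#' dropped with a message. Dosages are oriented to count minor-allele copies
#' (columns where the ALT allele is the major allele are flipped, swapping
#' the stored alleles accordingly).
#'
#' @param path VCF path (plain or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  bi <- !grepl(",", fix$ALT) & !is.na(fix$ALT)
  if (any(!bi)) {
    message("dropping ", sum(!bi), " multi-allelic VCF row(s)")
    v <- v[bi, ]
    fix <- fix[bi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    x <- gsub("\\|", "/", x)
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  dos <- t(apply(gt, 1L, count_alt))          # snps x samples
  dos <- t(dos)                               # samples x snps
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  snps <- data.frame(chr = fix$CHROM, id = ids, pos = as.integer(fix$POS),
                     a1 = fix$ALT, a2 = fix$REF, stringsAsFactors = FALSE)
  # orient to minor allele
  f <- colMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) {
    dos[, flip] <- 2L - dos[, flip]
    tmp <- snps$a1[flip]; snps$a1[flip] <- snps$a2[flip]; snps$a2[flip] <- tmp
  }
  genotype_matrix(dos, colnames(gt), snps)
}

# per-SNP mean imputation (returns a plain numeric matrix)
impute_dosage <- function(g) {
  d <- g$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2L]]
  }
  d
}
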
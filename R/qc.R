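#' Genotype quality control
#'
#' Applies, in order: sample call-rate filter, SNP minor-allele-frequency
#' filter, and removal of sex-chromosome (non-autosomal) SNPs. A report of
#' counts removed per filter is attached as attribute `"qc_report"` and
#' printed by [print_qc_report()].
#'
#' @param g A [genotype_matrix()].
#' @param sample_call_rate Minimum per-sample call rate (default 0.90; a
#'   sample is removed when its rate is below this).
#' @param snp_maf Minimum minor allele frequency (default 0.02).
#' @param autosomes_only Drop SNPs on `sex_chromosomes` (default `TRUE`).
#' @param sex_chromosomes Chromosome names treated as non-autosomal.
#' @return Filtered [genotype_matrix()] with a `"qc_report"` attribute.
#' @export
qc_filter <- function(g, sample_call_rate = 0.90, snp_maf = 0.02,
                      autosomes_only = TRUE,
                      sex_chromosomes = c("Z", "W", "X", "Y", "M", "MT")) {
  stopifnot(inherits(g, "genotype_matrix"))
  n0 <- length(g$samples); m0 <- nrow(g$snps)
  cr <- rowMeans(!is.na(g$dosage))
  keep_s <- cr >= sample_call_rate
  if (!any(keep_s)) stop("all samples removed by the call-rate filter",
                         call. = FALSE)
  g <- subset_genotypes(g, samples = which(keep_s))
  st <- snp_stats(g)
  keep_maf <- !is.na(st$maf) & st$maf >= snp_maf
  g <- subset_genotypes(g, snps = which(keep_maf))
  removed_sex <- 0L
  if (autosomes_only) {
    keep_chr <- !(g$snps$chr %in% sex_chromosomes)
    removed_sex <- sum(!keep_chr)
    g <- subset_genotypes(g, snps = which(keep_chr))
  }
  report <- data.frame(
    filter = c("sample_call_rate", "snp_maf", "sex_chromosomes"),
    threshold = c(sample_call_rate, snp_maf, NA),
    removed = c(n0 - sum(keep_s), sum(!keep_maf), removed_sex),
    remaining = c(sum(keep_s), m0 - sum(!keep_maf),
                  m0 - sum(!keep_maf) - removed_sex))
  attr(g, "qc_report") <- report
  g
}

#' @rdname qc_filter
#' @param x Output of [qc_filter()] (or the report itself).
#' @param file Optional path to also write the report as plain text.
#' @export
print_qc_report <- function(x, file = NULL) {
  rep <- if (is.data.frame(x)) x else attr(x, "qc_report")
  txt <- c("Genotype QC report",
           utils::capture.output(print(rep, row.names = FALSE)))
  if (!is.null(file)) writeLines(txt, file)
  cat(txt, sep = "\n")
  invisible(rep)
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window_snps` SNPs (advanced by `step_snps`) along each
#' chromosome; within a window, a SNP is dropped when its squared Pearson
#' correlation (on mean-imputed dosages) with any retained earlier SNP of the
#' window exceeds `r2_max`. After pruning, no retained pair within a window
#' has r-squared above the threshold.
#'
#' @param g A [genotype_matrix()].
#' @param r2_max Maximum allowed squared correlation (default 0.8).
#' @param window_snps,step_snps Window size and step in SNP counts
#'   (defaults 50 and 5).
#' @return Character vector of retained SNP ids (attribute `"index"` holds
#'   column indices).
#' @export
ld_prune <- function(g, r2_max = 0.8, window_snps = 50L, step_snps = 5L) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- impute_dosage(g)
  m <- ncol(d)
  keep <- rep(TRUE, m)
  for (ch in unique(g$snps$chr)) {
    idx <- which(g$snps$chr == ch)
    starts <- seq(1L, max(1L, length(idx) - 1L), by = step_snps)
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1L, length(idx))]
      w <- w[keep[w]]
      if (length(w) < 2L) next
      cc <- suppressWarnings(stats::cor(d[, w, drop = FALSE]))
      cc[is.na(cc)] <- 0
      for (a in seq_along(w)) {
        if (!keep[w[a]]) next
        if (a == length(w)) break
        for (b in seq(a + 1L, length(w))) {
          if (keep[w[b]] && cc[a, b]^2 > r2_max) keep[w[b]] <- FALSE
        }
      }
    }
  }
  out <- g$snps$id[keep]
  attr(out, "index") <- which(keep)
  out
}

#' Identity-by-state duplicate detection
#'
#' Pairwise IBS is the mean over SNPs non-missing in both samples of
#' `(2 - |g_i - g_j|) / 2`. Pairs above `threshold` are flagged as
#' duplicates; for each pair the later sample in id sort order is marked for
#' removal.
#'
#' @param g A [genotype_matrix()] with at least two samples.
#' @param threshold IBS threshold (default 0.98).
#' @return `data.frame` with `sample1`, `sample2`, `ibs`, `remove` (the
#'   member of the pair marked for removal); zero rows when no pair exceeds
#'   the threshold. The full IBS matrix is attached as attribute `"ibs"`.
#' @export
ibs_duplicates <- function(g, threshold = 0.98) {
  stopifnot(inherits(g, "genotype_matrix"), length(g$samples) >= 2L)
  d <- g$dosage
  obs <- !is.na(d)
  A <- list(`0` = (d == 0) & obs, `1` = (d == 1) & obs, `2` = (d == 2) & obs)
  A <- lapply(A, function(m) { m[is.na(m)] <- FALSE; m * 1 })
  nn <- tcrossprod(obs * 1)                      # shared non-missing counts
  absdiff <- tcrossprod(A[["0"]], A[["1"]]) + tcrossprod(A[["1"]], A[["0"]]) +
    tcrossprod(A[["1"]], A[["2"]]) + tcrossprod(A[["2"]], A[["1"]]) +
    2 * (tcrossprod(A[["0"]], A[["2"]]) + tcrossprod(A[["2"]], A[["0"]]))
  ibs <- 1 - absdiff / (2 * nn)
  dimnames(ibs) <- list(g$samples, g$samples)
  ut <- which(upper.tri(ibs) & ibs > threshold, arr.ind = TRUE)
  res <- data.frame(sample1 = g$samples[ut[, 1L]],
                    sample2 = g$samples[ut[, 2L]],
                    ibs = ibs[ut],
                    stringsAsFactors = FALSE)
  res$remove <- ifelse(res$sample1 > res$sample2, res$sample1, res$sample2)
  attr(res, "ibs") <- ibs
  res
}
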
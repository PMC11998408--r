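#' Genomic relatedness matrix (VanRaden, per-SNP scaling)
#'
#' Mean-imputes missing dosages, centers each SNP at twice its allele
#' frequency, scales by `sqrt(2 p (1 - p))` and averages the cross-product
#' over SNPs: `G = W W' / m` with `W[,k] = (g_k - 2 p_k) / sqrt(2 p_k (1 -
#' p_k))`. SNPs with zero variance after imputation are excluded and counted.
#'
#' @param g A [genotype_matrix()] (post-QC).
#' @return Object of class `"grm"`: `matrix` (n x n), `samples`, `snp_count`
#'   (SNPs used), `excluded` (zero-variance SNPs dropped).
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- impute_dosage(g)
  p <- colMeans(d) / 2
  v <- 2 * p * (1 - p)
  emp <- colMeans(d^2) - colMeans(d)^2
  ok <- v > 0 & emp > 0
  excluded <- sum(!ok)
  if (!any(ok)) stop("no polymorphic SNPs for the GRM", call. = FALSE)
  W <- sweep(d[, ok, drop = FALSE], 2L, 2 * p[ok], "-")
  W <- sweep(W, 2L, sqrt(v[ok]), "/")
  G <- tcrossprod(W) / sum(ok)
  dimnames(G) <- list(g$samples, g$samples)
  structure(list(matrix = G, samples = g$samples, snp_count = sum(ok),
                 excluded = excluded),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("GRM:", length(x$samples), "samples from", x$snp_count, "SNPs")
  if (x$excluded > 0L) cat(" (", x$excluded, "zero-variance SNPs excluded )")
  cat("\n  mean diagonal:", signif(mean(diag(x$matrix)), 4), "\n")
  invisible(x)
}

#' Write a GRM as a delimited lower triangle plus ids
#'
#' @param grm A `"grm"` object.
#' @param prefix Output prefix; writes `<prefix>.grm.tsv` (columns i, j,
#'   value for j <= i) and `<prefix>.grm.id`.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  idx <- which(lower.tri(grm$matrix, diag = TRUE), arr.ind = TRUE)
  tab <- data.frame(i = idx[, 1L], j = idx[, 2L],
                    value = grm$matrix[idx])
  write.table(tab, paste0(prefix, ".grm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(grm$samples, paste0(prefix, ".grm.id"))
  invisible(prefix)
}

# Eigenvalue clipping at zero; returns list(matrix, eigen) of the projected
# PSD matrix. Eigenvalues above `tol` are unchanged.
psd_project <- function(M, tol = 1e-8) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  clipped <- eg$values < 0
  if (any(clipped)) eg$values[clipped] <- 0
  list(values = eg$values, vectors = eg$vectors, n_clipped = sum(clipped))
}

#' Principal components of the genotypes via the GRM
#'
#' Eigendecomposes the PSD-projected GRM and returns the top-k components,
#' each eigenvector scaled by the square root of its eigenvalue. Sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param grm A `"grm"` object (or a plain symmetric matrix).
#' @param k Number of components (default 3; must be < n).
#' @return n x k matrix of sample scores, with attributes `"values"`
#'   (eigenvalues) and `"degenerate"` (`TRUE` when the leading eigenvalues
#'   are numerically all equal, e.g. an identity GRM).
#' @export
genotype_pca <- function(grm, k = 3L) {
  M <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  n <- nrow(M)
  if (k >= n) stop("k must be smaller than the number of samples",
                   call. = FALSE)
  eg <- psd_project(M)
  vals <- eg$values[seq_len(k)]
  vecs <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    imax <- which.max(abs(vecs[, j]))
    if (vecs[imax, j] < 0) vecs[, j] <- -vecs[, j]
  }
  pcs <- sweep(vecs, 2L, sqrt(pmax(vals, 0)), "*")
  rownames(pcs) <- rownames(M)
  colnames(pcs) <- paste0("PC", seq_len(k))
  spread <- diff(range(eg$values)) / max(abs(eg$values), 1e-300)
  attr(pcs, "values") <- vals
  attr(pcs, "degenerate") <- spread < 1e-8
  pcs
}
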
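#' Linear mixed model genome-wide association
#'
#' Tests each SNP in `y = W a + x b + u + e` with `u ~ N(0, Vg G)`. In
#' `mode = "approx"` the variance ratio is fixed at its null-model GREML
#' estimate and each SNP is tested by generalized least squares through the
#' GRM eigendecomposition (EMMAX-style, with the residual scale re-estimated
#' per SNP so that an identity GRM reduces exactly to the OLS t-test). In
#' `mode = "exact"` the ratio is re-optimized per SNP before the Wald test.
#' Missing dosages are mean-imputed; effects are per copy of the counted
#' (minor) allele.
#'
#' @param y Phenotype vector, named by sample id or aligned with `g`.
#' @param g A [genotype_matrix()].
#' @param covariates Optional fixed covariates (e.g. PCs).
#' @param grm Optional `"grm"` (default: computed from `g`).
#' @param null Optional `"greml"` fit to reuse (must match samples).
#' @param mode `"approx"` (default) or `"exact"`.
#' @return `data.frame` with one row per SNP: `chr`, `pos`, `id`, `beta`,
#'   `se_beta`, `maf`, `p_value`, `pve`. Attribute `"lambda_gc"` holds the
#'   genomic inflation factor of the scan.
#' @export
lmm_gwas <- function(y, g, covariates = NULL, grm = NULL, null = NULL,
                     mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(names(y))) {
    if (length(y) != length(g$samples)) {
      stop("unnamed phenotype must align with the genotype samples",
           call. = FALSE)
    }
    names(y) <- g$samples
  }
  if (is.null(grm)) grm <- compute_grm(g)
  if (!identical(grm$samples, g$samples)) {
    stop("samples misaligned between genotypes and GRM", call. = FALSE)
  }
  if (is.null(null)) null <- greml(y, grm, covariates = covariates, se = FALSE)
  pre <- null$pre
  gs <- if (!is.null(pre$samples) && !identical(pre$samples, g$samples)) {
    if (anyNA(match(pre$samples, g$samples))) {
      stop("samples misaligned between phenotype and genotypes", call. = FALSE)
    }
    subset_genotypes(g, samples = match(pre$samples, g$samples))
  } else g
  st <- snp_stats(gs)
  d <- impute_dosage(gs)
  Xs <- crossprod(pre$U, d)               # rotated dosages, n x m
  n <- pre$n; p <- pre$p
  lambda0 <- if (null$Ve > 0) null$Vg / null$Ve else 0
  m <- ncol(Xs)
  beta <- se <- pval <- rep(NA_real_, m)
  test_at <- function(lam, ysj, Wsj, xj) {
    w <- 1 / (lam * pre$d + 1)
    sw <- sqrt(w)
    Q <- qr(Wsj * sw)
    yr <- qr.resid(Q, ysj * sw)
    xr <- qr.resid(Q, xj * sw)
    sxx <- sum(xr^2)
    if (sxx < 1e-12) return(c(NA_real_, NA_real_, NA_real_))
    b <- sum(xr * yr) / sxx
    rss <- sum(yr^2) - b^2 * sxx
    df <- n - p - 1L
    s2 <- rss / df
    sb <- sqrt(s2 / sxx)
    c(b, sb, 2 * pt(-abs(b / sb), df))
  }
  if (mode == "approx") {
    w <- 1 / (lambda0 * pre$d + 1)
    sw <- sqrt(w)
    Q <- qr(pre$Ws * sw)
    yr <- qr.resid(Q, pre$ys * sw)
    Xr <- qr.resid(Q, Xs * sw)
    sxx <- colSums(Xr^2)
    ok <- sxx > 1e-12
    b <- ifelse(ok, colSums(Xr * yr) / sxx, NA_real_)
    yry <- sum(yr^2)
    df <- n - p - 1L
    s2 <- (yry - b^2 * sxx) / df
    sb <- sqrt(s2 / sxx)
    beta <- b; se <- sb
    pval <- 2 * pt(-abs(b / sb), df)
  } else {
    for (j in seq_len(m)) {
      opt <- optimize(function(ll) {
        lam <- exp(ll)
        w <- 1 / (lam * pre$d + 1)
        sw <- sqrt(w)
        WX <- cbind(pre$Ws, Xs[, j]) * sw
        Q <- qr(WX)
        yr <- qr.resid(Q, pre$ys * sw)
        rss <- sum(yr^2)
        Ve <- rss / (n - p - 1L)
        R <- qr.R(Q)
        -0.5 * (sum(log(lam * pre$d + 1)) + (n - p - 1L) * log(Ve) +
                  2 * sum(log(abs(diag(R)))))
      }, interval = c(-12, 12), maximum = TRUE, tol = 1e-8)
      res <- test_at(exp(opt$maximum), pre$ys, pre$Ws, Xs[, j])
      beta[j] <- res[1L]; se[j] <- res[2L]; pval[j] <- res[3L]
    }
  }
  pve <- rep(NA_real_, m)
  okm <- !is.na(st$maf) & st$maf > 0 & is.finite(beta) & is.finite(se) & se > 0
  pve[okm] <- snp_pve(beta[okm], se[okm], st$maf[okm], n)
  out <- data.frame(chr = gs$snps$chr, pos = gs$snps$pos, id = gs$snps$id,
                    beta = beta, se_beta = se, maf = st$maf,
                    p_value = pval, pve = pve,
                    stringsAsFactors = FALSE)
  ok <- is.finite(out$p_value) & out$p_value > 0
  attr(out, "lambda_gc") <- if (sum(ok) >= 100L)
    genomic_inflation(out$p_value[ok]) else NA_real_
  out
}

#' Genomic inflation factor (lambda)
#'
#' Median of the 1-df chi-square quantiles of the p-values divided by the
#' median of the chi-square(1) distribution (0.4549364). Values near 1
#' indicate a calibrated scan.
#'
#' @param p_values Vector of at least 100 p-values in `(0, 1]`.
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) < 100L) {
    stop("need at least 100 p-values for a stable lambda", call. = FALSE)
  }
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  chi <- qchisq(p_values, df = 1L, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1L)
}

#' Bonferroni significance thresholds
#'
#' Genome-wide threshold `alpha / m` and suggestive threshold `1 / m`
#' (one expected false positive per genome scan).
#'
#' @param m Number of tests (SNPs), `>= 1`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Named list with `genomewide` and `suggestive`.
#' @export
#' @examples
#' bonferroni_thresholds(2940003)
bonferroni_thresholds <- function(m, alpha = 0.05) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("`m` must be a single count >= 1", call. = FALSE)
  }
  list(genomewide = alpha / m, suggestive = 1 / m)
}

#' Proportion of phenotypic variance explained by a SNP
#'
#' `pve = [2 b^2 maf (1 - maf)] / [2 b^2 maf (1 - maf) + se(b)^2 2 N maf (1 -
#' maf)]`, which reduces algebraically to `b^2 / (b^2 + N se^2)` (the allele
#' frequency cancels).
#'
#' @param beta SNP effect(s).
#' @param se_beta Standard error(s), `> 0`.
#' @param maf Minor allele frequency in `(0, 0.5]`.
#' @param N Sample size, `> 0`.
#' @return Proportion(s) in `[0, 1)`.
#' @export
#' @examples
#' snp_pve(-0.132, 0.025, 0.384, 1586)  # ~0.0173
snp_pve <- function(beta, se_beta, maf, N) {
  stopifnot(N > 0)
  if (any(!is.na(se_beta) & se_beta <= 0)) {
    stop("se_beta must be positive", call. = FALSE)
  }
  if (any(!is.na(maf) & (maf <= 0 | maf > 0.5))) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  num <- 2 * beta^2 * maf * (1 - maf)
  num / (num + se_beta^2 * 2 * N * maf * (1 - maf))
}
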
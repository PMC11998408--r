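#' Restricted log-likelihood of the GREML model at fixed variances
#'
#' Exact REML log-likelihood (including constants) of
#' `y = W a + u + e`, `u ~ N(0, Vg G)`, `e ~ N(0, Ve I)`, evaluated through
#' the eigendecomposition of `G`. Useful for diagnostics and cross-checks
#' against a direct dense evaluation.
#'
#' @param Vg,Ve Genomic and residual variances (`>= 0`, not both zero).
#' @param y Phenotype vector.
#' @param grm A `"grm"` object (or symmetric matrix) aligned with `y`.
#' @param covariates Optional matrix of fixed covariates (an intercept is
#'   always added).
#' @return The restricted log-likelihood (scalar).
#' @export
greml_loglik <- function(Vg, Ve, y, grm, covariates = NULL) {
  pre <- greml_prepare(y, grm, covariates)
  greml_loglik_rotated(Vg, Ve, pre)
}

greml_prepare <- function(y, grm, covariates = NULL, rotation = NULL) {
  if (!is.null(rotation)) {
    # reuse an existing eigendecomposition/covariate rotation; y must be
    # complete and aligned with the rotation's samples
    stopifnot(length(y) == rotation$n, !anyNA(y))
    if (!is.null(names(y)) && !is.null(rotation$samples)) {
      y <- y[rotation$samples]
    }
    rotation$ys <- drop(crossprod(rotation$U, y))
    return(rotation)
  }
  M <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  if (!is.null(names(y)) && !is.null(rownames(M))) {
    common <- intersect(names(y), rownames(M))
    if (!length(common)) stop("no overlapping sample ids between phenotype ",
                              "and GRM", call. = FALSE)
    idx <- match(common, rownames(M))
    y <- y[common]
    M <- M[idx, idx]
    if (!is.null(covariates)) {
      covariates <- as.matrix(covariates)[idx, , drop = FALSE]
    }
  }
  W <- cbind(`(Intercept)` = rep(1, length(y)))
  if (!is.null(covariates)) W <- cbind(W, as.matrix(covariates))
  cc <- complete.cases(cbind(y, W))
  y <- y[cc]; W <- W[cc, , drop = FALSE]; M <- M[cc, cc]
  eg <- psd_project(M)
  list(ys = drop(crossprod(eg$vectors, y)),
       Ws = crossprod(eg$vectors, W),
       d = eg$values, n = length(y), p = ncol(W),
       U = eg$vectors, samples = rownames(M))
}

greml_loglik_rotated <- function(Vg, Ve, pre) {
  v <- Vg * pre$d + Ve
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  WtW <- crossprod(pre$Ws * sqrt(w))
  ch <- tryCatch(chol(WtW), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  b <- backsolve(ch, forwardsolve(t(ch), crossprod(pre$Ws, w * pre$ys)))
  r <- pre$ys - drop(pre$Ws %*% b)
  yPy <- sum(w * r^2)
  -0.5 * ((pre$n - pre$p) * log(2 * pi) + sum(log(v)) +
            2 * sum(log(diag(ch))) + yPy)
}

# profile restricted loglik over the ratio lambda = Vg/Ve; returns the
# loglik and the profiled Ve
greml_profile <- function(lambda, pre) {
  w <- 1 / (lambda * pre$d + 1)
  if (any(!is.finite(w)) || any(w <= 0)) return(list(ll = -Inf, Ve = NA))
  WtW <- crossprod(pre$Ws * sqrt(w))
  ch <- tryCatch(chol(WtW), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf, Ve = NA))
  b <- backsolve(ch, forwardsolve(t(ch), crossprod(pre$Ws, w * pre$ys)))
  r <- pre$ys - drop(pre$Ws %*% b)
  rss <- sum(w * r^2)
  Ve <- rss / (pre$n - pre$p)
  ll <- -0.5 * ((pre$n - pre$p) * log(2 * pi) + sum(log(lambda * pre$d + 1)) +
                  (pre$n - pre$p) * log(Ve) + 2 * sum(log(diag(ch))) +
                  (pre$n - pre$p))
  list(ll = ll, Ve = Ve, beta = drop(b))
}

#' GREML: genomic heritability via restricted maximum likelihood
#'
#' Estimates the genomic (`Vg`) and residual (`Ve`) variance of a phenotype
#' under `y = W a + u + e` with `u ~ N(0, Vg G)`. A single eigendecomposition
#' of the (PSD-projected) GRM reduces REML to a one-dimensional optimization
#' of the variance ratio. The null model (`Vg = 0`) is fitted for a
#' likelihood-ratio test whose null distribution is the 50:50 mixture of a
#' point mass at zero and chi-square(1) (one variance on the boundary).
#'
#' @param y Phenotype vector; if named, matched to GRM sample ids.
#'   Incomplete cases are dropped.
#' @param grm A `"grm"` object (or symmetric relatedness matrix).
#' @param covariates Optional fixed covariates (e.g. [genotype_pca()]
#'   scores); an intercept is always included.
#' @param se Compute standard errors from the numerically inverted observed
#'   information (default `TRUE`).
#' @param interval Search interval for `log(Vg/Ve)`.
#' @param rotation A previous fit's `$pre` element: reuse its GRM
#'   eigendecomposition and covariate rotation when fitting many phenotypes
#'   on the same samples (y must be complete and aligned).
#' @return Object of class `"greml"` with `Vg`, `Ve`, `h2`, their SEs,
#'   `loglik_full`, `loglik_null`, `lrt`, `lrt_p`, `fixed` (GLS solutions),
#'   `n` and the rotation (`pre`) for reuse in [lmm_gwas()].
#' @export
greml <- function(y, grm = NULL, covariates = NULL, se = TRUE,
                  interval = c(-12, 12), rotation = NULL) {
  if (is.null(grm) && is.null(rotation)) {
    stop("either `grm` or `rotation` is required", call. = FALSE)
  }
  pre <- greml_prepare(y, grm, covariates, rotation = rotation)
  opt <- optimize(function(ll) greml_profile(exp(ll), pre)$ll,
                  interval = interval, maximum = TRUE, tol = 1e-10)
  null <- greml_profile(0, pre)
  best <- greml_profile(exp(opt$maximum), pre)
  if (null$ll >= best$ll) {       # boundary solution Vg = 0
    lambda <- 0; best <- null
  } else {
    lambda <- exp(opt$maximum)
  }
  Ve <- best$Ve
  Vg <- lambda * Ve
  h2 <- if (Vg + Ve > 0) Vg / (Vg + Ve) else NA_real_
  ll_full <- best$ll
  lrt <- max(0, 2 * (ll_full - null$ll))
  lrt_p <- 0.5 * pchisq(lrt, df = 1L, lower.tail = FALSE)
  ses <- c(Vg = NA_real_, Ve = NA_real_, h2 = NA_real_)
  if (se && lambda > 0) {
    H <- tryCatch(numeric_hessian(function(th)
      greml_loglik_rotated(th[1L], th[2L], pre), c(Vg, Ve)),
      error = function(e) NULL)
    if (!is.null(H)) {
      Cov <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(Cov) && all(diag(Cov) > 0)) {
        ses["Vg"] <- sqrt(Cov[1L, 1L]); ses["Ve"] <- sqrt(Cov[2L, 2L])
        gr <- c(Ve, -Vg) / (Vg + Ve)^2
        v_h2 <- drop(t(gr) %*% Cov %*% gr)
        if (is.finite(v_h2) && v_h2 >= 0) ses["h2"] <- sqrt(v_h2)
      }
    }
  }
  structure(list(Vg = Vg, Ve = Ve, h2 = h2,
                 se_Vg = ses[["Vg"]], se_Ve = ses[["Ve"]],
                 se_h2 = ses[["h2"]],
                 loglik_full = ll_full, loglik_null = null$ll,
                 lrt = lrt, lrt_p = lrt_p,
                 fixed = best$beta, n = pre$n, pre = pre),
            class = "greml")
}

numeric_hessian <- function(f, x, rel = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x) * rel, 1e-10)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.greml <- function(x, ...) {
  cat("GREML fit (n =", x$n, ")\n")
  tab <- data.frame(estimate = c(x$Vg, x$Ve, x$h2),
                    se = c(x$se_Vg, x$se_Ve, x$se_h2),
                    row.names = c("Vg", "Ve", "h2"))
  print(signif(tab, 4))
  cat("LRT (Vg = 0):", signif(x$lrt, 4), " p =", signif(x$lrt_p, 3), "\n")
  invisible(x)
}

#' @export
summary.greml <- function(object, ...) {
  print(object)
  cat("logLik full:", object$loglik_full, " null:", object$loglik_null, "\n")
  invisible(object)
}
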
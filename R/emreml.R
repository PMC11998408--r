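#' EM-REML for a mixed model with per-individual random regressions
#'
#' Fits `y = X b + Z u + e` where `u` stacks one coefficient vector per
#' individual, `u_i ~ N(0, Sigma)` i.i.d. across individuals and
#' `e ~ N(0, sigma2_e I)`. `Sigma` is either a scalar (`structure = "iid"`,
#' random intercepts) or an unstructured `k x k` covariance
#' (`structure = "unstructured"`). Variance components are estimated by
#' EM-REML over the mixed-model equations; each individual's equations are
#' absorbed analytically, so cost per iteration is linear in the number of
#' individuals. The restricted log-likelihood (up to a constant) is recorded
#' at every iteration and is non-decreasing.
#'
#' @param y Numeric response vector (length N).
#' @param X Fixed-effects design matrix (N x p, full rank).
#' @param id Individual identifier per record (length N).
#' @param Z Random-regression covariate rows (N x k matrix; for
#'   `structure = "iid"` typically a single column of ones).
#' @param structure `"iid"` (scalar variance, k must be 1) or
#'   `"unstructured"` (full k x k covariance).
#' @param tol Convergence tolerance on the relative change of the restricted
#'   log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000). Non-convergence is
#'   flagged, not raised.
#' @param var_floor Lower floor applied to variance-component eigenvalues to
#'   keep the equations solvable near the parameter boundary.
#' @param fixed_components Optional `list(sigma =, sigma_e =)`: hold the
#'   variance components at these values and solve the mixed-model equations
#'   once (no EM updates), e.g. to obtain GLS fixed-effect solutions and
#'   BLUPs at known truth.
#' @return List of class `"emreml"`: `beta` (fixed solutions), `beta_cov`,
#'   `u` (q x k BLUP matrix, rows named by individual), `sigma` (k x k),
#'   `sigma_e`, `loglik_trace`, `converged`, `iterations`,
#'   `psd_projections` (count of covariance projections applied), `ids`.
#' @export
emreml_fit <- function(y, X, id, Z,
                       structure = c("unstructured", "iid"),
                       tol = 1e-8, max_iter = 1000L, var_floor = 1e-10,
                       fixed_components = NULL) {
  structure <- match.arg(structure)
  X <- as.matrix(X); Z <- as.matrix(Z)
  N <- length(y); p <- ncol(X); k <- ncol(Z)
  stopifnot(nrow(X) == N, nrow(Z) == N, length(id) == N)
  if (structure == "iid" && k != 1L) {
    stop("structure = \"iid\" requires a single random-regression column",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("fixed-effects design is singular; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  id <- as.character(id)
  ids <- sort(unique(id))
  q <- length(ids)
  gi <- match(id, ids)
  if (structure == "unstructured") {
    cnt <- tabulate(gi, q)
    if (any(cnt < 2L)) {
      stop("unstructured covariance needs >= 2 records per individual",
           call. = FALSE)
    }
  }
  ord <- order(gi)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; Z <- Z[ord, , drop = FALSE]
  gi <- gi[ord]

  # Per-individual sufficient statistics.
  ZtZ <- array(0, c(q, k, k))        # Z_i' Z_i
  XtZ <- array(0, c(q, p, k))        # X_i' Z_i
  Zty <- matrix(0, q, k)             # Z_i' y_i
  for (a in seq_len(k)) {
    Zty[, a] <- rowsum(Z[, a] * y, gi)[, 1L]
    for (b in seq_len(a)) {
      v <- rowsum(Z[, a] * Z[, b], gi)[, 1L]
      ZtZ[, a, b] <- v; ZtZ[, b, a] <- v
    }
    for (m in seq_len(p)) XtZ[, m, a] <- rowsum(X[, m] * Z[, a], gi)[, 1L]
  }
  XtX <- crossprod(X); Xty <- crossprod(X, y)[, 1L]; yty <- sum(y * y)

  # Group individuals sharing a Z_i' Z_i pattern (common in balanced designs)
  # so the k x k factorizations are done once per pattern.
  pat_key <- apply(matrix(signif(ZtZ, 12), q), 1L, paste, collapse = ",")
  pat <- match(pat_key, unique(pat_key))
  npat <- max(pat)
  pat_rows <- split(seq_len(q), pat)
  pat_first <- vapply(pat_rows, `[`, integer(1L), 1L)
  pat_n <- lengths(pat_rows)

  vy <- stats::var(y)
  sigma_e <- vy / 2
  Sigma <- diag(vy / (2 * k), k)
  if (!is.null(fixed_components)) {
    Sigma <- as.matrix(fixed_components$sigma)
    sigma_e <- fixed_components$sigma_e
    max_iter <- 1L
  }
  loglik <- rep(NA_real_, max_iter)
  psd_projections <- 0L
  converged <- FALSE
  sym <- function(M) (M + t(M)) / 2

  for (iter in seq_len(max_iter)) {
    Lam <- solve(Sigma)
    Dinv <- vector("list", npat); logdetD <- numeric(npat); Rt <- vector("list", npat)
    for (pp in seq_len(npat)) {
      D <- matrix(ZtZ[pat_first[pp], , ], k, k) / sigma_e + Lam
      ch <- chol(D)
      logdetD[pp] <- 2 * sum(log(diag(ch)))
      Di <- chol2inv(ch)
      Dinv[[pp]] <- Di
      Rt[[pp]] <- t(chol(sym(Di) + diag(1e-300, k)))   # Di = Rt %*% t(Rt)
    }
    B <- XtZ / sigma_e                                  # q x p x k
    r <- Zty / sigma_e                                  # q x k
    # c_i = Dinv_i r_i, per pattern
    cmat <- matrix(0, q, k)
    BR <- array(0, c(q, p, k))                          # B_i %*% Rt (per pattern)
    for (pp in seq_len(npat)) {
      rows <- pat_rows[[pp]]
      cmat[rows, ] <- r[rows, , drop = FALSE] %*% t(Dinv[[pp]])
      Rp <- Rt[[pp]]
      for (a in seq_len(k)) {
        acc <- 0
        for (l in seq_len(k)) if (Rp[l, a] != 0)
          acc <- acc + B[rows, , l, drop = FALSE] * Rp[l, a]
        BR[rows, , a] <- acc
      }
    }
    # S = X'X/se - sum_i B_i Dinv_i B_i' ; absorption of the random equations
    absorb <- matrix(0, p, p)
    for (a in seq_len(k)) absorb <- absorb + crossprod(matrix(BR[, , a], q, p))
    S <- XtX / sigma_e - absorb
    rhs_b <- Xty / sigma_e -
      rowSums(vapply(seq_len(k), function(a)
        colSums(matrix(B[, , a], q, p) * cmat[, a]), numeric(p)))
    chS <- chol(sym(S))
    Sinv <- chol2inv(chS)
    beta <- drop(Sinv %*% rhs_b)
    # u_i = Dinv_i (r_i - B_i' beta)
    Bb <- vapply(seq_len(k), function(a)
      drop(matrix(B[, , a], q, p) %*% beta), numeric(q))  # q x k
    resid_r <- r - Bb
    u <- matrix(0, q, k)
    for (pp in seq_len(npat)) {
      rows <- pat_rows[[pp]]
      u[rows, ] <- resid_r[rows, , drop = FALSE] %*% t(Dinv[[pp]])
    }
    # y'Py and restricted log-likelihood (constant terms dropped)
    yPy <- yty / sigma_e - sum(beta * Xty) / sigma_e - sum(u * r)
    logdetSigma <- determinant(Sigma, logarithm = TRUE)$modulus[1L]
    m2ll <- N * log(sigma_e) + q * logdetSigma + sum(pat_n * logdetD) +
      2 * sum(log(diag(chS))) + yPy
    loglik[iter] <- -0.5 * m2ll

    if (!is.null(fixed_components)) { converged <- TRUE; break }
    if (iter > 1L) {
      rel <- abs(loglik[iter] - loglik[iter - 1L]) /
        (abs(loglik[iter - 1L]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }

    # EM updates. PEV_i = Dinv_i + (B_i Dinv_i)' Sinv (B_i Dinv_i); the full
    # Dinv (not its factor) multiplies B here.
    half <- t(chol(sym(Sinv) + diag(1e-300, p)))        # Sinv = half %*% t(half)
    BD <- array(0, c(q, p, k))                          # B_i %*% Dinv_i
    for (pp in seq_len(npat)) {
      rows <- pat_rows[[pp]]
      Dp <- Dinv[[pp]]
      for (a in seq_len(k)) {
        acc <- 0
        for (l in seq_len(k)) if (Dp[l, a] != 0)
          acc <- acc + B[rows, , l, drop = FALSE] * Dp[l, a]
        BD[rows, , a] <- acc
      }
    }
    HS <- array(0, c(q, k, p))
    for (a in seq_len(k)) HS[, a, ] <- matrix(BD[, , a], q, p) %*% half
    pev_sum <- matrix(0, k, k)
    for (pp in seq_len(npat)) {
      rows <- pat_rows[[pp]]
      blk <- matrix(0, k, k)
      for (a in seq_len(k)) for (b in seq_len(a)) {
        v <- sum(HS[rows, a, ] * HS[rows, b, ])
        blk[a, b] <- v; blk[b, a] <- v
      }
      pev_sum <- pev_sum + pat_n[pp] * Dinv[[pp]] + blk
    }
    Sigma_new <- sym(crossprod(u) + pev_sum) / q
    eg <- eigen(Sigma_new, symmetric = TRUE)
    if (any(eg$values < var_floor)) {
      psd_projections <- psd_projections + 1L
      Sigma_new <- eg$vectors %*% diag(pmax(eg$values, var_floor), k) %*%
        t(eg$vectors)
      Sigma_new <- sym(Sigma_new)
    }
    sigma_e_new <- (yty - sum(beta * Xty) - sum(u * Zty)) / (N - p)
    Sigma <- Sigma_new
    sigma_e <- max(sigma_e_new, var_floor)
  }
  iterations <- if (converged) iter else max_iter
  if (!converged) {
    warning("EM-REML did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  rownames(u) <- ids
  structure(list(beta = setNames(beta, colnames(X)), beta_cov = Sinv,
                 u = u, sigma = Sigma, sigma_e = sigma_e,
                 loglik_trace = loglik[seq_len(iterations)],
                 converged = converged, iterations = iterations,
                 psd_projections = psd_projections, ids = ids,
                 n_records = N, n_individuals = q),
            class = "emreml")
}

#' @export
print.emreml <- function(x, ...) {
  cat("EM-REML fit:", x$n_records, "records,", x$n_individuals,
      "individuals\n")
  cat("  sigma_e =", signif(x$sigma_e, 6), "\n")
  if (nrow(x$sigma) == 1L) {
    cat("  sigma_u =", signif(x$sigma[1L, 1L], 6), "\n")
  } else {
    cat("  Sigma_u:\n"); print(signif(x$sigma, 6))
  }
  cat("  restricted logLik:", signif(tail(x$loglik_trace, 1L), 8),
      if (x$converged) paste0("(converged in ", x$iterations, " iterations)")
      else "(NOT converged)", "\n")
  invisible(x)
}
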
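# small random-regression dataset with known architecture
sim_rr <- function(q = 30, nrec = 7, Sigma = diag(c(1, 0.3, 0.2)),
                   sd_e = 0.8, seed = 1, beta = c(4, 1, -0.5, 0.7)) {
  set.seed(seed)
  id <- rep(sprintf("i%03d", seq_len(q)), each = nrec)
  xs <- rep(seq(-1, 1, length.out = nrec), q)
  Z <- legendre_row(xs)
  X <- cbind(Z, cov1 = rep(rnorm(q), each = nrec))
  u <- matrix(rnorm(q * 3), q, 3) %*% chol(Sigma + diag(1e-12, 3))
  y <- drop(X %*% beta) + rowSums(Z * u[match(id, unique(id)), ]) +
    rnorm(q * nrec, 0, sd_e)
  list(y = y, X = X, Z = Z, id = id, u = u, Sigma = Sigma, sd_e = sd_e,
       beta = beta)
}

test_that("solutions at fixed components equal a dense GLS oracle", {
  d <- sim_rr(q = 10, seed = 3)
  fit <- emreml_fit(d$y, d$X, d$id, d$Z,
                    fixed_components = list(sigma = d$Sigma,
                                            sigma_e = d$sd_e^2))
  # dense GLS: V = Z* G Z*' + se I with Z* the blocked design
  N <- length(d$y); q <- 10
  gi <- match(d$id, sort(unique(d$id)))
  Zfull <- matrix(0, N, 3 * q)
  for (r in seq_len(N)) Zfull[r, (gi[r] - 1) * 3 + 1:3] <- d$Z[r, ]
  V <- Zfull %*% kronecker(diag(q), d$Sigma) %*% t(Zfull) +
    diag(d$sd_e^2, N)
  Vi <- solve(V)
  b_gls <- solve(t(d$X) %*% Vi %*% d$X, t(d$X) %*% Vi %*% d$y)
  expect_equal(unname(fit$beta), unname(drop(b_gls)), tolerance = 1e-8)
  # BLUPs: u = G Z' Vinv (y - Xb)
  u_blup <- kronecker(diag(q), d$Sigma) %*% t(Zfull) %*% Vi %*%
    (d$y - d$X %*% b_gls)
  expect_equal(as.vector(t(fit$u)), drop(u_blup), tolerance = 1e-8)
})

test_that("true null individual variance is recovered as (near) zero", {
  set.seed(8)
  q <- 80; nrec <- 7
  id <- rep(sprintf("i%03d", 1:q), each = nrec)
  X <- cbind(1, rnorm(q * nrec))
  y <- drop(X %*% c(2, 1)) + rnorm(q * nrec, 0, 0.05)
  fit <- suppressWarnings(
    emreml_fit(y, X, id, matrix(1, q * nrec, 1), structure = "iid",
               tol = 1e-12, max_iter = 5000))
  expect_lt(fit$sigma[1, 1], 1e-3 * fit$sigma_e)
})

test_that("the restricted log-likelihood trace is monotone on every fit", {
  for (s in 1:5) {
    d <- sim_rr(q = 25, seed = s, Sigma = crossprod(matrix(rnorm(9), 3)))
    fit <- suppressWarnings(emreml_fit(d$y, d$X, d$id, d$Z, max_iter = 300))
    expect_true(all(diff(fit$loglik_trace) > -1e-7))
  }
})

test_that("variance components are recovered in a moderate simulation", {
  # scalar intercept structure: compare against lme4 as independent oracle
  d <- sim_rr(q = 150, seed = 10, Sigma = diag(c(1.5, 0, 0)), sd_e = 1)
  fit <- emreml_fit(d$y, d$X, d$id, matrix(1, length(d$y), 1),
                    structure = "iid")
  expect_equal(fit$sigma[1, 1], 1.5, tolerance = 0.5)
  skip_if_not_installed("lme4")
  df <- data.frame(y = d$y, id = d$id)
  X <- d$X
  m <- lme4::lmer(y ~ 0 + X + (1 | id), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$sigma[1, 1], vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma_e, vc$vcov[2], tolerance = 1e-3)
  expect_equal(unname(fit$beta), unname(lme4::fixef(m)), tolerance = 1e-4)
})

test_that("unstructured covariance estimates approach lme4's", {
  skip_if_not_installed("lme4")
  d <- sim_rr(q = 120, seed = 12,
              Sigma = matrix(c(1, 0.3, 0, 0.3, 0.5, 0.1, 0, 0.1, 0.4), 3),
              sd_e = 0.7)
  fit <- suppressWarnings(
    emreml_fit(d$y, d$X, d$id, d$Z, tol = 1e-10, max_iter = 3000))
  df <- data.frame(y = d$y, id = d$id, p1 = d$Z[, 2], p2 = d$Z[, 3])
  X <- d$X
  m <- lme4::lmer(y ~ 0 + X + (1 + p1 + p2 | id), data = df, REML = TRUE,
                  control = lme4::lmerControl(
                    check.conv.singular = "ignore"))
  vc <- lme4::VarCorr(m)$id
  expect_equal(unname(diag(fit$sigma)), unname(diag(vc)), tolerance = 0.05)
  expect_equal(fit$sigma_e, attr(lme4::VarCorr(m), "sc")^2, tolerance = 0.02)
})

test_that("a singular fixed design errors naming the collinear column", {
  d <- sim_rr(q = 10, seed = 5)
  X_bad <- cbind(d$X, dup = d$X[, 1] + d$X[, 2])
  expect_error(emreml_fit(d$y, X_bad, d$id, d$Z), "collinear.*dup|dup")
})

test_that("unstructured fits require two records per individual", {
  d <- sim_rr(q = 10, seed = 6)
  keep <- !(d$id == "i001" & duplicated(d$id))
  expect_error(emreml_fit(d$y[keep], d$X[keep, ], d$id[keep],
                          d$Z[keep, ], structure = "unstructured"),
               ">= 2 records")
})
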
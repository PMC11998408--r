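test_that("the population norm recovers designed coefficients", {
  td <- tiny_growth_data(n_per_batch = 40, seed = 31, a = c(10, 2, -1))
  prep <- prepare_growth_data(td$weights, td$weather)
  fit <- fit_population_norm(prep, "tavg", "mean")
  expect_true(fit$fit$converged)
  # generous 3-SE window for a single-seed check
  expect_true(all(abs(fit$norm$coef - td$a) <= 3 * fit$norm$se))
  # growth increasing in the covariate here, so the linear term is positive
  expect_gt(fit$norm$coef[["a1"]], 0)
})

test_that("a constant covariate makes the norm inestimable", {
  td <- tiny_growth_data(n_per_batch = 3)
  prep <- prepare_growth_data(td$weights, td$weather)
  # rh is engineered constant at 50
  expect_error(fit_population_norm(prep, "rh", "mean"), "constant")
})

test_that("unmatched growth weeks are reported", {
  td <- tiny_growth_data(n_per_batch = 3)
  prep <- prepare_growth_data(td$weights, td$weather)
  prep$covariates <- prep$covariates[prep$covariates$batch == 1, ]
  expect_error(fit_population_norm(prep, "tavg", "mean"), "without a matched")
})

test_that("fitted values are invariant to the factor reference level", {
  td <- tiny_growth_data(n_per_batch = 8, seed = 33)
  prep1 <- prepare_growth_data(td$weights, td$weather)
  prep2 <- prep1
  # flip the sex labels' sort order to change the reference level
  prep2$records$sex <- factor(prep2$records$sex,
                              levels = c("M", "F"))
  f1 <- fit_population_norm(prep1, "tavg", "mean")
  f2 <- fit_population_norm(prep2, "tavg", "mean")
  fitted_of <- function(f, prep) {
    xs <- standardize(resilnorm:::match_covariate(prep, "tavg", "mean"),
                      f$norm$range, warn = FALSE)
    Phi <- legendre_row(xs)
    X <- resilnorm:::fixed_design(prep$records, Phi)
    drop(X %*% f$fit$beta) +
      f$intercept_deviations[as.character(prep$records$chicken_id)]
  }
  expect_equal(unname(fitted_of(f1, prep1)), unname(fitted_of(f2, prep2)),
               tolerance = 1e-8)
})

test_that("individual deviations shrink to zero under a shared profile", {
  td <- tiny_growth_data(n_per_batch = 25, seed = 35, sd_int = 0,
                         sd_res = 0.4)
  prep <- prepare_growth_data(td$weights, td$weather)
  fit <- suppressWarnings(fit_individual_norms(prep, "tavg", "mean",
                                               max_iter = 400))
  expect_lt(max(abs(fit$deviations)), 0.15)
  expect_lt(max(diag(fit$Sigma_a)), 0.05)
})

test_that("deviation BLUPs average to (practically) zero per coefficient", {
  cfg <- sim_config(seed = 51, n_chickens = 250, h2_dev = 0,
                    Sigma_a = diag(c(1.5, 0.3, 0.3)))
  w <- simulate_weather(cfg)
  sim <- simulate_growth(cfg, w, NULL)
  prep <- prepare_growth_data(sim$weights, w)
  fit <- suppressWarnings(
    fit_individual_norms(prep, "thi", "mean", max_iter = 600))
  sds <- apply(fit$deviations, 2, sd)
  means <- abs(colMeans(fit$deviations))
  expect_true(all(means < 0.05 * pmax(sds, 1e-8)))
  expect_true(all(eigen(fit$Sigma_a, symmetric = TRUE,
                        only.values = TRUE)$values >= 0))
  # deviation summary table has the median/SEM/SD layout
  s <- summary(fit)
  expect_equal(names(s), c("coefficient", "median", "sem", "sd"))
  expect_equal(s$sem, s$sd / sqrt(nrow(fit$deviations)))
})

test_that("deviation covariance is recovered on well-identified simulations", {
  Sigma_true <- diag(c(1.2, 0.4, 0.25))
  Sigma_true[1, 2] <- Sigma_true[2, 1] <- -0.3
  reps <- 4
  est <- array(NA_real_, c(reps, 3, 3))
  for (r in seq_len(reps)) {
    cfg <- sim_config(seed = 600 + r, n_chickens = 600, h2_dev = 0,
                      Sigma_a = Sigma_true, residual_sd = 0.8)
    w <- simulate_weather(cfg)
    sim <- simulate_growth(cfg, w, NULL)
    prep <- prepare_growth_data(sim$weights, w)
    fit <- suppressWarnings(
      fit_individual_norms(prep, "thi", "mean", max_iter = 1500))
    est[r, , ] <- fit$Sigma_a
  }
  m <- apply(est, c(2, 3), mean)
  mcse <- apply(est, c(2, 3), sd) / sqrt(reps)
  expect_true(all(abs(m - Sigma_true) <= 3 * pmax(mcse, 0.05)))
})

test_that("correlation SEs reproduce the (1-r^2)/sqrt(n-3) worked values", {
  expect_equal(round(correlation_se(0.79, 1590), 2), 0.01)
  expect_equal(correlation_se(0.79, 1590), 0.00944, tolerance = 1e-3)
  expect_equal(round(correlation_se(-0.51, 1590), 2), 0.02)
  expect_equal(correlation_se(-0.51, 1590), 0.01857, tolerance = 1e-3)
  expect_equal(correlation_se(1, 100), 0)
  expect_error(correlation_se(1.2, 100))
})

test_that("coefficient correlations come with SEs and flag degeneracy", {
  td <- tiny_growth_data(n_per_batch = 20, seed = 37)
  prep <- prepare_growth_data(td$weights, td$weather)
  fit <- suppressWarnings(fit_individual_norms(prep, "tavg", "mean",
                                               max_iter = 300))
  cc <- coeff_correlations(fit)
  expect_equal(cc$pair, c("a0_a1", "a0_a2"))
  expect_true(all(abs(cc$r) <= 1))
  expect_equal(cc$se, (1 - cc$r^2) / sqrt(cc$n - 3))
  # zero-variance coefficient -> NA with warning
  fit$deviations[, 2] <- 0
  expect_warning(cc2 <- coeff_correlations(fit), "zero-variance")
  expect_true(is.na(cc2$r[1]))
})
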
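rng <- standardization_range(14, 18)
pop <- reaction_norm(c(12, 1.5, -0.8), rng, variable = "thi",
                     statistic = "mean")

test_that("individual norms are the coefficientwise sum", {
  expect_equal(individual_reaction_norms(pop, c(0, 0, 0))$coef, pop$coef)
  up <- individual_reaction_norms(pop, c(1, 0, 0))
  x <- seq(14, 18, length.out = 20)
  expect_equal(curve_eval(up, x), curve_eval(pop, x) + 1)
  expect_equal(curve_derivative(up, x), curve_derivative(pop, x))
  set.seed(9)
  dv <- rnorm(3)
  both <- individual_reaction_norms(pop, dv)
  devn <- reaction_norm(dv, rng)
  expect_equal(curve_eval(both, x), curve_eval(pop, x) + curve_eval(devn, x))
})

test_that("basis/range mismatches are rejected", {
  dev_bad <- reaction_norm(c(1, 0, 0), standardization_range(0, 1))
  expect_error(individual_reaction_norms(pop, dev_bad), "mismatch")
})

test_that("evaluation points honour overrides and straddle the maximum", {
  expect_equal(select_evaluation_points(pop, overrides = c(15, 17)),
               c(15, 17))
  expect_error(select_evaluation_points(pop, overrides = c(13, 17)),
               "outside")
  # concave norm with interior vertex: auto points straddle it
  conc <- reaction_norm(c(0, 0, -1), rng)
  pts <- select_evaluation_points(conc)
  xm <- as.numeric(curve_argmax(conc))
  expect_lt(pts[1], xm); expect_gt(pts[2], xm)
  # monotone convex norm: both points on one side, warned
  mono <- reaction_norm(c(0, 1, 1), rng)
  expect_warning(pts2 <- select_evaluation_points(mono), "boundary|monotone")
  xm2 <- as.numeric(curve_argmax(mono))
  expect_true(all(pts2 < xm2) || all(pts2 > xm2))
})

test_that("slopes equal finite differences of each individual curve", {
  set.seed(10)
  devs <- matrix(rnorm(30, 0, 0.5), 10, 3,
                 dimnames = list(sprintf("c%02d", 1:10), NULL))
  norms <- individual_reaction_norms(pop, devs)
  ph <- derive_resilience(norms, c(15, 17))
  expect_equal(nrow(ph), 20L)
  for (i in seq_len(nrow(ph))) {
    nm <- norms[[ph$chicken_id[i]]]
    h <- 1e-5
    fd <- (curve_eval(nm, ph$point[i] + h) -
             curve_eval(nm, ph$point[i] - h)) / (2 * h)
    expect_equal(ph$slope[i], fd, tolerance = 1e-6)
  }
})

test_that("zero quadratic and zero deviations give one shared slope", {
  lin <- reaction_norm(c(10, 2, 0), rng)
  norms <- individual_reaction_norms(
    lin, matrix(0, 5, 3, dimnames = list(letters[1:5], NULL)))
  ph <- derive_resilience(norms, c(15, 17))
  expect_equal(length(unique(round(ph$slope, 12))), 1L)
  expect_equal(unique(ph$slope), 2 * 2 / 4)   # chain rule: 2/(upper-lower)
})

test_that("intercept-only deviations change no slope", {
  set.seed(11)
  base <- matrix(rnorm(15), 5, 3, dimnames = list(letters[1:5], NULL))
  shifted <- base; shifted[, 1] <- shifted[, 1] + 5
  p1 <- derive_resilience(individual_reaction_norms(pop, base), c(15, 17))
  p2 <- derive_resilience(individual_reaction_norms(pop, shifted), c(15, 17))
  expect_equal(p1$slope, p2$slope)
})

test_that("summaries match a direct oracle and flag zero means", {
  ph <- data.frame(chicken_id = c("a", "b", "c"), variable = "thi",
                   statistic = "mean", point = 15,
                   slope = c(1, 2, 3))
  s <- summarize_resilience(ph)
  expect_equal(s$mean, 2); expect_equal(s$sd, 1); expect_equal(s$cv_pct, 50)
  expect_equal(s$se, 1 / sqrt(3)); expect_equal(s$median, 2)
  same <- ph; same$slope <- 1.3
  s2 <- summarize_resilience(same)
  expect_equal(s2$sd, 0); expect_equal(s2$cv_pct, 0)
  zero <- ph; zero$slope <- c(-1, 0, 1)
  expect_warning(s3 <- summarize_resilience(zero), "CV undefined")
  expect_true(is.na(s3$cv_pct))
  set.seed(12)
  rnd <- ph[rep(1, 50), ]; rnd$chicken_id <- sprintf("c%02d", 1:50)
  rnd$slope <- rnorm(50)
  s4 <- summarize_resilience(rnd)
  expect_equal(s4$mean, mean(rnd$slope))
  expect_equal(s4$sd, sd(rnd$slope))
  expect_equal(s4$min, min(rnd$slope)); expect_equal(s4$max, max(rnd$slope))
})

test_that("resilience slopes are invariant to basis normalization", {
  td <- tiny_growth_data(n_per_batch = 15, seed = 41)
  prep <- prepare_growth_data(td$weights, td$weather)
  fp <- suppressWarnings(fit_individual_norms(prep, "tavg", "mean",
                                              normalized = FALSE,
                                              max_iter = 500, tol = 1e-10))
  fn <- suppressWarnings(fit_individual_norms(prep, "tavg", "mean",
                                              normalized = TRUE,
                                              max_iter = 500, tol = 1e-10))
  pts <- c(15, 17)
  php <- derive_resilience(individual_reaction_norms(fp$norm, fp), pts)
  phn <- derive_resilience(individual_reaction_norms(fn$norm, fn), pts)
  # converged fits agree up to EM stopping error; exact invariance at
  # matched variance components is asserted elsewhere at 1e-8
  expect_equal(php$slope, phn$slope, tolerance = 1e-3)
})

test_that("mean individual slope tracks the population slope", {
  cfg <- sim_config(seed = 52, n_chickens = 250, h2_dev = 0,
                    Sigma_a = diag(c(1.5, 0.3, 0.3)))
  w <- simulate_weather(cfg)
  sim <- simulate_growth(cfg, w, NULL)
  prep <- prepare_growth_data(sim$weights, w)
  fit <- suppressWarnings(fit_individual_norms(prep, "thi", "mean",
                                               max_iter = 600))
  pts <- suppressWarnings(select_evaluation_points(fit$norm))
  ph <- derive_resilience(individual_reaction_norms(fit$norm, fit), pts)
  for (p in pts) {
    sl <- ph$slope[ph$point == p]
    expect_lte(abs(mean(sl) - curve_derivative(fit$norm, p)),
               0.05 * max(sd(sl), 1e-6))
  }
})

test_that("phenotype files are written one per point", {
  ph <- data.frame(chicken_id = rep(c("a", "b"), 2), variable = "thi",
                   statistic = "mean", point = rep(c(15, 17), each = 2),
                   slope = 1:4)
  dir <- file.path(tempdir(), "resout")
  paths <- write_resilience_phenotypes(ph, dir)
  expect_length(list.files(dir, pattern = "^resilience_"), 2L)
  back <- read.table(list.files(dir, pattern = "^resilience_",
                                full.names = TRUE)[1],
                     header = TRUE, sep = "\t")
  expect_equal(names(back), c("chicken_id", "slope"))
  unlink(dir, recursive = TRUE)
})
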
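rng14 <- standardization_range(14, 18)

test_that("standardization maps range endpoints and midpoint", {
  expect_equal(as.numeric(standardize(14, rng14)), -1)
  expect_equal(as.numeric(standardize(18, rng14)), 1)
  expect_equal(as.numeric(standardize(16, rng14)), 0)
  expect_error(standardization_range(5, 5), "degenerate")
})

test_that("out-of-range values clip with a flag", {
  expect_warning(standardize(c(13, 19, 16), rng14), "clipped")
  xs <- standardize(c(13, 19, 16), rng14, warn = FALSE)
  expect_equal(as.numeric(xs), c(-1, 1, 0))
  expect_equal(attr(xs, "clipped"), c(TRUE, TRUE, FALSE))
})

test_that("Legendre basis rows match the polynomial definitions", {
  expect_equal(drop(legendre_row(0)), c(phi0 = 1, phi1 = 0, phi2 = -0.5))
  expect_equal(drop(legendre_row(1)), c(phi0 = 1, phi1 = 1, phi2 = 1))
  expect_equal(drop(legendre_row(0.5, normalized = TRUE)),
               c(phi0 = 0.70711, phi1 = 0.61237, phi2 = -0.19764),
               tolerance = 1e-4)
})

test_that("curve evaluation agrees with a Horner-form oracle", {
  set.seed(5)
  for (r in 1:10) {
    a <- rnorm(3)
    norm <- reaction_norm(a, rng14)
    x <- runif(20, 14, 18)
    xs <- 2 * (x - 14) / 4 - 1
    # expand a0 + a1 x + a2 (3x^2-1)/2 into monomial form, Horner evaluate
    c0 <- a[1] - a[3] / 2; c1 <- a[2]; c2 <- 1.5 * a[3]
    horner <- c0 + xs * (c1 + xs * c2)
    expect_equal(curve_eval(norm, x), horner, tolerance = 1e-12)
  }
  expect_equal(curve_eval(reaction_norm(c(5, 0, 0), rng14), c(14, 15.7, 18)),
               rep(5, 3))
  expect_equal(curve_eval(reaction_norm(c(0, 1, 0), rng14), 18), 1)
})

test_that("analytic slope matches a central finite difference", {
  set.seed(6)
  for (r in 1:10) {
    norm <- reaction_norm(rnorm(3), rng14, normalized = r %% 2 == 0)
    x <- runif(5, 14.1, 17.9)
    h <- 1e-5
    fd <- (curve_eval(norm, x + h) - curve_eval(norm, x - h)) / (2 * h)
    an <- curve_derivative(norm, x)
    expect_equal(an, fd, tolerance = 1e-6)
  }
  # constant-norm slope is zero; pure linear slope is 2/(upper-lower)
  expect_equal(curve_derivative(reaction_norm(c(3, 0, 0), rng14), 15:17),
               rep(0, 3))
  expect_equal(curve_derivative(reaction_norm(c(0, 1, 0), rng14), 15:17),
               rep(0.5, 3))
})

test_that("argmax agrees with a dense grid-search oracle", {
  grid <- seq(14, 18, length.out = 10001)
  set.seed(7)
  for (r in 1:20) {
    norm <- reaction_norm(rnorm(3), rng14, normalized = r %% 3 == 0)
    xm <- curve_argmax(norm)
    gm <- grid[which.max(curve_eval(norm, grid))]
    expect_lte(abs(as.numeric(xm) - gm), diff(grid[1:2]) + 1e-12)
  }
  # symmetric concave vertex at the midpoint
  expect_equal(as.numeric(curve_argmax(reaction_norm(c(0, 0, -1), rng14))), 16)
  # increasing convex curve peaks at the upper boundary
  expect_equal(as.numeric(curve_argmax(reaction_norm(c(0, 1, 1), rng14))), 18)
  # flat curve: midpoint, flagged degenerate
  flat <- curve_argmax(reaction_norm(c(2, 0, 0), rng14))
  expect_true(attr(flat, "degenerate"))
  expect_equal(as.numeric(flat), 16)
  # symmetric convex curve: equal boundary values, tie broken to the lower
  expect_equal(as.numeric(curve_argmax(reaction_norm(c(0, 0, 1), rng14))), 14)
})

test_that("plain and normalized bases fit identical curves", {
  td <- tiny_growth_data(n_per_batch = 10, seed = 21)
  prep <- prepare_growth_data(td$weights, td$weather)
  fp <- fit_population_norm(prep, "tavg", "mean", normalized = FALSE)
  fn <- fit_population_norm(prep, "tavg", "mean", normalized = TRUE)
  x <- seq(fp$norm$range$lower, fp$norm$range$upper, length.out = 17)
  expect_equal(curve_eval(fp$norm, x), curve_eval(fn$norm, x),
               tolerance = 1e-6)
  expect_equal(curve_derivative(fp$norm, x), curve_derivative(fn$norm, x),
               tolerance = 1e-6)
  # the coefficients themselves differ (different basis scaling)
  expect_false(isTRUE(all.equal(fp$norm$coef, fn$norm$coef)))
})

test_that("reaction norms serialize and read back exactly", {
  norms <- list(reaction_norm(c(1.5, -0.2, 0.33), rng14, se = c(0.1, 0.2, 0.3),
                              variable = "tavg", statistic = "mean"),
                reaction_norm(c(0, 1, 2), standardization_range(0, 1),
                              normalized = TRUE, variable = "rh",
                              statistic = "variance"))
  f <- tempfile(fileext = ".tsv")
  write_reaction_norms(norms, f)
  back <- read_reaction_norms(f)
  expect_equal(back[[1]]$coef, norms[[1]]$coef)
  expect_equal(back[[1]]$se, norms[[1]]$se)
  expect_equal(back[[2]]$range, norms[[2]]$range)
  expect_true(back[[2]]$normalized)
  expect_null(back[[2]]$se)
})
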
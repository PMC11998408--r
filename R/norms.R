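fixed_design <- function(records, Phi) {
  df <- data.frame(sex = factor(records$sex),
                   batch_season = factor(records$batch_season))
  mm <- model.matrix(~ sex + batch_season, df)
  X <- cbind(Phi, mm[, -1L, drop = FALSE])
  colnames(X) <- c(colnames(Phi), colnames(mm)[-1L])
  X
}

norm_covariate <- function(data, variable, statistic, range) {
  x <- match_covariate(data, variable, statistic)
  if (is.null(range)) {
    if (diff(range(x)) <= 0) {
      stop("covariate `", variable, "` (", statistic, ") is constant across ",
           "weeks: linear and quadratic terms are inestimable", call. = FALSE)
    }
    range <- standardization_range(min(x), max(x))
  } else if (is.numeric(range)) {
    range <- standardization_range(range[1L], range[2L])
  }
  list(x = x, range = range)
}

#' Fit the population reaction norm (fixed quadratic regression)
#'
#' Weekly growth is modelled as fixed effects (sex and combined
#' batch-by-season, reference-level coded) plus a fixed second-degree
#' Legendre regression on the standardized weekly weather covariate (the
#' population norm), a random i.i.d. intercept per individual, and a
#' residual. Solved by EM-REML. One fit corresponds to one
#' (variable, statistic) pair; mapping over all pairs reproduces a full
#' population-norm table.
#'
#' @param data A [prepare_growth_data()] object.
#' @param variable Weather variable name (e.g. `"thi"`).
#' @param statistic `"mean"` or `"variance"` of the daily values in the week.
#' @param normalized Use the orthonormal Legendre scaling (fitted curves are
#'   invariant to this flag).
#' @param range Optional standardization range (default: observed min/max of
#'   the weekly covariate).
#' @param tol,max_iter Passed to [emreml_fit()].
#' @return Object of class `"rn_fit1"`: `norm` (a [reaction_norm()] with
#'   SEs), `var_a` (individual intercept variance), `var_e`, `fixed`
#'   (all fixed-effect solutions and SEs), `intercept_deviations`, and the
#'   underlying `"emreml"` fit.
#' @export
fit_population_norm <- function(data, variable = "thi", statistic = "mean",
                                normalized = FALSE, range = NULL,
                                tol = 1e-8, max_iter = 1000L) {
  cv <- norm_covariate(data, variable, statistic, range)
  records <- data$records
  xs <- standardize(cv$x, cv$range, warn = FALSE)
  Phi <- legendre_row(xs, normalized)
  X <- fixed_design(records, Phi)
  fit <- emreml_fit(records$growth, X, records$chicken_id,
                    matrix(1, nrow(X), 1L), structure = "iid",
                    tol = tol, max_iter = max_iter)
  se <- sqrt(diag(fit$beta_cov))
  norm <- reaction_norm(fit$beta[1:3], cv$range, normalized = normalized,
                        se = se[1:3], variable = variable,
                        statistic = statistic)
  structure(list(norm = norm, var_a = fit$sigma[1L, 1L], var_e = fit$sigma_e,
                 fixed = data.frame(term = names(fit$beta),
                                    estimate = unname(fit$beta),
                                    se = unname(se)),
                 intercept_deviations = setNames(fit$u[, 1L], fit$ids),
                 fit = fit, variable = variable, statistic = statistic),
            class = "rn_fit1")
}

#' Fit individual deviation reaction norms (random regressions)
#'
#' Extends [fit_population_norm()] by giving every individual its own random
#' second-degree Legendre deviation from the population norm, with an
#' unstructured 3 x 3 covariance across the intercept, linear and quadratic
#' deviation coefficients. Deviations are BLUPs and hence shrunken toward
#' zero; on balanced data their means are approximately zero by
#' construction.
#'
#' @inheritParams fit_population_norm
#' @return Object of class `"rn_fit2"`: `norm` (population part),
#'   `deviations` (individuals x 3 BLUP matrix), `Sigma_a`, `var_e`, `fixed`
#'   and the underlying `"emreml"` fit.
#' @export
fit_individual_norms <- function(data, variable = "thi", statistic = "mean",
                                 normalized = FALSE, range = NULL,
                                 tol = 1e-8, max_iter = 1000L) {
  cv <- norm_covariate(data, variable, statistic, range)
  if (length(unique(cv$x)) < 3L) {
    stop("fewer than 3 distinct covariate values: quadratic deviations are ",
         "inestimable", call. = FALSE)
  }
  records <- data$records
  xs <- standardize(cv$x, cv$range, warn = FALSE)
  Phi <- legendre_row(xs, normalized)
  X <- fixed_design(records, Phi)
  fit <- emreml_fit(records$growth, X, records$chicken_id, Phi,
                    structure = "unstructured", tol = tol,
                    max_iter = max_iter)
  se <- sqrt(diag(fit$beta_cov))
  norm <- reaction_norm(fit$beta[1:3], cv$range, normalized = normalized,
                        se = se[1:3], variable = variable,
                        statistic = statistic)
  dev <- fit$u
  colnames(dev) <- c("a0", "a1", "a2")
  structure(list(norm = norm, deviations = dev, Sigma_a = fit$sigma,
                 var_e = fit$sigma_e,
                 fixed = data.frame(term = names(fit$beta),
                                    estimate = unname(fit$beta),
                                    se = unname(se)),
                 fit = fit, variable = variable, statistic = statistic),
            class = "rn_fit2")
}

#' @export
print.rn_fit1 <- function(x, ...) {
  cat("Population reaction norm fit (", x$variable, ", ", x$statistic,
      ")\n", sep = "")
  print(x$norm)
  cat("var(individual intercept) =", signif(x$var_a, 5),
      " var(residual) =", signif(x$var_e, 5), "\n")
  invisible(x)
}

#' @export
coef.rn_fit1 <- function(object, ...) object$norm$coef

#' @export
predict.rn_fit1 <- function(object, newdata, ...) curve_eval(object$norm, newdata)

#' @export
summary.rn_fit1 <- function(object, ...) {
  out <- list(norm = object$norm, fixed = object$fixed,
              var_a = object$var_a, var_e = object$var_e,
              converged = object$fit$converged,
              iterations = object$fit$iterations)
  class(out) <- "summary.rn_fit1"
  out
}

#' @export
print.summary.rn_fit1 <- function(x, ...) {
  print(x$norm)
  cat("\nFixed effects:\n"); print(x$fixed, row.names = FALSE)
  cat("\nvar_a =", signif(x$var_a, 5), " var_e =", signif(x$var_e, 5),
      " (", x$iterations, "EM iterations )\n")
  invisible(x)
}

#' @export
print.rn_fit2 <- function(x, ...) {
  cat("Individual deviation reaction norm fit (", x$variable, ", ",
      x$statistic, ")\n", sep = "")
  print(x$norm)
  cat("Deviation covariance Sigma_a:\n")
  print(signif(x$Sigma_a, 5))
  cat("var(residual) =", signif(x$var_e, 5), "\n")
  invisible(x)
}

#' @export
coef.rn_fit2 <- function(object, ...) object$norm$coef

#' @export
predict.rn_fit2 <- function(object, newdata, ...) curve_eval(object$norm, newdata)

#' Per-coefficient summary of the individual deviation norms
#'
#' Median, standard error of the mean (SD/sqrt(n)) and standard deviation of
#' the BLUP deviation coefficients across individuals.
#'
#' @param object An `"rn_fit2"` fit.
#' @param ... Unused.
#' @return `data.frame` with one row per coefficient.
#' @export
summary.rn_fit2 <- function(object, ...) {
  d <- object$deviations
  data.frame(coefficient = colnames(d),
             median = apply(d, 2L, median),
             sem = apply(d, 2L, sd) / sqrt(nrow(d)),
             sd = apply(d, 2L, sd),
             row.names = NULL)
}

#' Correlations between deviation-norm coefficients
#'
#' Product-moment correlations of the individual intercept deviation with the
#' linear and quadratic deviations, with the approximate standard error
#' `(1 - r^2) / sqrt(n - 3)`.
#'
#' @param fit An `"rn_fit2"` object.
#' @param n Sample size for the SE (default: individuals in the fit).
#' @return `data.frame` with columns `pair`, `r`, `n`, `se`. An undefined
#'   correlation (zero-variance coefficient) is reported as `NA` with a
#'   warning.
#' @export
#' @seealso [correlation_se()]
coeff_correlations <- function(fit, n = NULL) {
  stopifnot(inherits(fit, "rn_fit2"))
  d <- fit$deviations
  if (is.null(n)) n <- nrow(d)
  if (n < 4L) stop("need n >= 4 for the correlation SE", call. = FALSE)
  sds <- apply(d, 2L, sd)
  one <- function(jcol, pair) {
    if (sds[1L] == 0 || sds[jcol] == 0) {
      warning("zero-variance coefficient: correlation for ", pair,
              " undefined", call. = FALSE)
      r <- NA_real_
    } else {
      r <- cor(d[, 1L], d[, jcol])
    }
    data.frame(pair = pair, r = r, n = n, se = correlation_se(r, n))
  }
  rbind(one(2L, "a0_a1"), one(3L, "a0_a2"))
}

#' Approximate standard error of a correlation
#'
#' `se = (1 - r^2) / sqrt(n - 3)`; zero when `|r| = 1`.
#'
#' @param r Correlation estimate(s) in `[-1, 1]`.
#' @param n Sample size (> 3).
#' @return Standard error(s).
#' @export
#' @examples
#' correlation_se(0.79, 1590)   # ~0.0094
correlation_se <- function(r, n) {
  stopifnot(all(is.na(r) | abs(r) <= 1), n > 3)
  (1 - r^2) / sqrt(n - 3)
}

#' Assemble a population-norm table across fits
#'
#' @param fits List of `"rn_fit1"` or `"rn_fit2"` objects.
#' @return `data.frame` with one row per fit: variable, statistic,
#'   coefficients and SEs.
#' @export
population_norm_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    n <- f$norm
    data.frame(variable = n$variable, statistic = n$statistic,
               a0 = n$coef[[1L]], se_a0 = n$se[[1L]],
               a1 = n$coef[[2L]], se_a1 = n$se[[2L]],
               a2 = n$coef[[3L]], se_a2 = n$se[[3L]],
               stringsAsFactors = FALSE)
  }))
}
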
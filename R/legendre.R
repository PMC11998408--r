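#' Covariate standardization range
#'
#' The range used to map a weather covariate onto the Legendre domain
#' `[-1, 1]`. In fitting, the observed minimum and maximum of the weekly
#' covariate are used and stored with the fitted norm, so that derivatives in
#' natural weather units are reproducible.
#'
#' @param lower,upper Range endpoints in covariate units; `upper > lower`.
#' @return Object of class `"standardization_range"`.
#' @export
standardization_range <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (!is.finite(lower) || !is.finite(upper) || upper <= lower) {
    stop("degenerate standardization range: need upper > lower", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "standardization_range")
}

#' Standardize a covariate to `[-1, 1]`
#'
#' `x_star = 2 (x - lower) / (upper - lower) - 1`. Values outside the range
#' are clipped to the nearest endpoint (quadratic extrapolation outside the
#' observed environmental range is unbounded and not meaningful for
#' resilience); clipping is flagged via attribute `"clipped"` and a warning.
#'
#' @param x Covariate values (natural units).
#' @param range A [standardization_range()].
#' @param warn Warn when clipping occurs (default `TRUE`).
#' @return Numeric vector in `[-1, 1]` with logical attribute `"clipped"`.
#' @export
standardize <- function(x, range, warn = TRUE) {
  stopifnot(inherits(range, "standardization_range"))
  xs <- 2 * (x - range$lower) / (range$upper - range$lower) - 1
  clipped <- !is.na(xs) & (xs < -1 | xs > 1)
  if (any(clipped) && warn) {
    warning(sum(clipped), " covariate value(s) outside the standardization ",
            "range were clipped", call. = FALSE)
  }
  xs <- pmin(pmax(xs, -1), 1)
  attr(xs, "clipped") <- clipped
  xs
}

# Normalization constants sqrt((2k+1)/2) for k = 0, 1, 2.
legendre_norm_const <- sqrt((2 * (0:2) + 1) / 2)

#' Second-degree Legendre basis row(s)
#'
#' Evaluates the Legendre polynomials P0, P1, P2 at standardized covariate
#' values. With `normalized = TRUE` each polynomial is scaled by
#' `sqrt((2k+1)/2)` (the orthonormal basis common in random-regression
#' software); the fitted curve is invariant to this choice.
#'
#' @param x_star Standardized covariate value(s) in `[-1, 1]`.
#' @param normalized Use the orthonormal scaling? Default `FALSE` (plain).
#' @return Matrix with one row per value and columns `phi0`, `phi1`, `phi2`.
#' @export
#' @examples
#' legendre_row(0)            # (1, 0, -0.5)
#' legendre_row(0.5, TRUE)
legendre_row <- function(x_star, normalized = FALSE) {
  stopifnot(all(is.na(x_star) | (x_star >= -1 & x_star <= 1)))
  m <- cbind(phi0 = rep(1, length(x_star)),
             phi1 = as.numeric(x_star),
             phi2 = (3 * as.numeric(x_star)^2 - 1) / 2)
  if (normalized) m <- sweep(m, 2L, legendre_norm_const, "*")
  m
}

# First derivatives of the basis wrt x_star.
legendre_row_deriv <- function(x_star, normalized = FALSE) {
  m <- cbind(phi0 = rep(0, length(x_star)),
             phi1 = rep(1, length(x_star)),
             phi2 = 3 * as.numeric(x_star))
  if (normalized) m <- sweep(m, 2L, legendre_norm_const, "*")
  m
}

#' Construct a reaction norm
#'
#' A quadratic reaction norm: three Legendre coefficients (intercept, linear,
#' quadratic) together with the covariate standardization range and the basis
#' scaling they refer to. Used for population norms, individual deviation
#' norms and combined individual norms.
#'
#' @param coef Numeric length-3 vector `(a0, a1, a2)`.
#' @param range A [standardization_range()] (or `c(lower, upper)`).
#' @param normalized Logical basis flag (see [legendre_row()]).
#' @param se Optional length-3 standard errors.
#' @param variable,statistic Optional labels (weather variable, mean/variance).
#' @return Object of class `"reaction_norm"`.
#' @export
reaction_norm <- function(coef, range, normalized = FALSE, se = NULL,
                          variable = NA_character_, statistic = NA_character_) {
  if (is.numeric(range) && length(range) == 2L) {
    range <- standardization_range(range[1L], range[2L])
  }
  stopifnot(inherits(range, "standardization_range"),
            is.numeric(coef), length(coef) == 3L, all(is.finite(coef)))
  structure(list(coef = setNames(as.numeric(coef), c("a0", "a1", "a2")),
                 range = range, normalized = isTRUE(normalized),
                 se = if (!is.null(se)) setNames(as.numeric(se), c("a0", "a1", "a2")),
                 variable = variable, statistic = statistic),
            class = "reaction_norm")
}

#' @export
print.reaction_norm <- function(x, ...) {
  lab <- if (!is.na(x$variable)) paste0(" [", x$variable, ", ", x$statistic, "]") else ""
  cat("Quadratic reaction norm", lab, "\n", sep = "")
  co <- rbind(estimate = x$coef)
  if (!is.null(x$se)) co <- rbind(co, se = x$se)
  print(round(co, 4))
  cat("covariate range: [", x$range$lower, ", ", x$range$upper, "], basis: ",
      if (x$normalized) "normalized" else "plain", "\n", sep = "")
  invisible(x)
}

#' @export
coef.reaction_norm <- function(object, ...) object$coef

#' Evaluate a reaction norm at covariate values
#'
#' @param norm A [reaction_norm()].
#' @param x Covariate values in natural units (clipped to the range).
#' @param warn Warn on clipping.
#' @return Growth values (g/day).
#' @export
curve_eval <- function(norm, x, warn = FALSE) {
  stopifnot(inherits(norm, "reaction_norm"))
  xs <- standardize(x, norm$range, warn = warn)
  drop(legendre_row(xs, norm$normalized) %*% norm$coef)
}

#' @export
predict.reaction_norm <- function(object, newdata, ...) {
  curve_eval(object, newdata)
}

#' Tangent slope of a reaction norm, in natural covariate units
#'
#' Analytic derivative of [curve_eval()] with the chain rule through the
#' standardization: for the plain basis,
#' `slope = (2 / (upper - lower)) * (a1 + 3 a2 x_star)`; the normalized basis
#' is scaled equivalently. The result is growth change per natural weather
#' unit (g/day per degree C, per percent humidity, per mm, ...).
#'
#' @inheritParams curve_eval
#' @return Slopes, g/day per covariate unit.
#' @export
curve_derivative <- function(norm, x, warn = FALSE) {
  stopifnot(inherits(norm, "reaction_norm"))
  xs <- standardize(x, norm$range, warn = warn)
  jac <- 2 / (norm$range$upper - norm$range$lower)
  drop(legendre_row_deriv(xs, norm$normalized) %*% norm$coef) * jac
}

#' Location of the maximum of a reaction norm on its range
#'
#' For a concave quadratic the interior vertex (mapped back to covariate
#' units); otherwise the range boundary with the larger curve value (the
#' lower boundary on an exact tie). A flat curve returns the range midpoint
#' flagged `degenerate`.
#'
#' @param norm A [reaction_norm()].
#' @return The maximizing covariate value, with logical attributes
#'   `"interior"` and `"degenerate"`.
#' @export
curve_argmax <- function(norm) {
  stopifnot(inherits(norm, "reaction_norm"))
  a <- norm$coef
  k <- if (norm$normalized) legendre_norm_const else c(1, 1, 1)
  # curve in x_star: const + c1 x* + c2 x*^2
  c1 <- a[["a1"]] * k[2L]
  c2 <- 1.5 * a[["a2"]] * k[3L]
  lo <- norm$range$lower; up <- norm$range$upper
  unmap <- function(xs) lo + (xs + 1) * (up - lo) / 2
  interior <- FALSE; degenerate <- FALSE
  if (c2 == 0 && c1 == 0) {
    xs <- 0; degenerate <- TRUE
  } else if (c2 < 0) {
    v <- -c1 / (2 * c2)
    if (v >= -1 && v <= 1) {
      xs <- v; interior <- TRUE
    } else {
      xs <- if (v < -1) -1 else 1
    }
  } else {
    flo <- curve_eval(norm, lo); fup <- curve_eval(norm, up)
    xs <- if (fup > flo) 1 else -1   # tie -> lower boundary
  }
  structure(unmap(xs), interior = interior, degenerate = degenerate)
}

#' Serialize reaction norms to a flat delimited table
#'
#' One row per norm: labels, coefficients, standard errors (if any), range
#' and basis flag. [read_reaction_norms()] inverts this.
#'
#' @param norms A single [reaction_norm()] or a list of them.
#' @param path Output file path (tab-separated).
#' @export
write_reaction_norms <- function(norms, path) {
  if (inherits(norms, "reaction_norm")) norms <- list(norms)
  rows <- lapply(norms, function(n) {
    data.frame(variable = n$variable, statistic = n$statistic,
               a0 = n$coef[[1L]], a1 = n$coef[[2L]], a2 = n$coef[[3L]],
               se_a0 = if (is.null(n$se)) NA_real_ else n$se[[1L]],
               se_a1 = if (is.null(n$se)) NA_real_ else n$se[[2L]],
               se_a2 = if (is.null(n$se)) NA_real_ else n$se[[3L]],
               lower = n$range$lower, upper = n$range$upper,
               normalized = n$normalized, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_reaction_norms
#' @return `read_reaction_norms()` returns a list of [reaction_norm()]s.
#' @export
read_reaction_norms <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    se <- unlist(d[i, c("se_a0", "se_a1", "se_a2")])
    reaction_norm(unlist(d[i, c("a0", "a1", "a2")]),
                  standardization_range(d$lower[i], d$upper[i]),
                  normalized = d$normalized[i],
                  se = if (all(is.na(se))) NULL else se,
                  variable = d$variable[i], statistic = d$statistic[i])
  })
}
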
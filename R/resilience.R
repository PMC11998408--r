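#' Combine population norm and individual deviations into individual norms
#'
#' An individual's reaction norm is the coefficientwise sum of the population
#' norm and the individual's deviation triple; range and basis are inherited
#' (and must match if the deviation carries its own).
#'
#' @param pop Population [reaction_norm()].
#' @param deviations Either a single length-3 deviation vector, a matrix with
#'   one row per individual (as in `fit$deviations`), or an `"rn_fit2"` fit.
#' @return A single [reaction_norm()] for a vector input, otherwise a named
#'   list of [reaction_norm()]s.
#' @export
individual_reaction_norms <- function(pop, deviations) {
  if (inherits(deviations, "rn_fit2")) {
    pop2 <- deviations$norm
    if (!isTRUE(all.equal(pop$range, pop2$range)) ||
        pop$normalized != pop2$normalized) {
      stop("population norm and fit use different basis/range", call. = FALSE)
    }
    deviations <- deviations$deviations
  }
  if (inherits(deviations, "reaction_norm")) {
    if (!isTRUE(all.equal(pop$range, deviations$range)) ||
        pop$normalized != deviations$normalized) {
      stop("basis/range mismatch between population norm and deviation",
           call. = FALSE)
    }
    deviations <- deviations$coef
  }
  mk <- function(dv) {
    reaction_norm(pop$coef + dv, pop$range, normalized = pop$normalized,
                  variable = pop$variable, statistic = pop$statistic)
  }
  if (is.numeric(deviations) && is.null(dim(deviations))) {
    stopifnot(length(deviations) == 3L)
    return(mk(deviations))
  }
  deviations <- as.matrix(deviations)
  stopifnot(ncol(deviations) == 3L)
  out <- lapply(seq_len(nrow(deviations)), function(i) mk(deviations[i, ]))
  names(out) <- rownames(deviations)
  out
}

#' Bundled default evaluation points
#'
#' Two evaluation points (covariate units) for each of the 12 standard norms
#' (weekly mean and weekly variance of the six weather variables), placed on
#' either side of the typical population-curve maximum.
#'
#' @return `data.frame` with `variable`, `statistic`, `P_low`, `P_high`.
#' @export
resilience_point_defaults <- function() {
  data.frame(
    variable = rep(c("tmax", "tmin", "tavg", "rh", "thi", "precip"), 2L),
    statistic = rep(c("mean", "variance"), each = 6L),
    P_low = c(22, 8, 15, 50, 15.5, 3, 1.18, 1.16, 0.53, 35, 0.4, 100),
    P_high = c(26, 11, 17, 70, 16.5, 13, 4.18, 3.16, 1.53, 95, 1.2, 250),
    stringsAsFactors = FALSE
  )
}

#' Choose the two evaluation points of a reaction norm
#'
#' Resilience phenotypes are tangent slopes at two covariate values, one on
#' either side of the curve's maximum. Explicit `overrides` (e.g. the bundled
#' defaults from [resilience_point_defaults()]) are used verbatim after a
#' range check. Otherwise the points start at the 25th/75th percentile
#' positions of the standardization range and are nudged to straddle
#' [curve_argmax()]; when the maximum sits on a boundary (monotone curve on
#' the range) both points fall on the monotone side and a warning is issued.
#'
#' @param pop Population [reaction_norm()].
#' @param overrides Optional numeric length-2 `c(P_low, P_high)`.
#' @return Numeric `c(P_low, P_high)` in covariate units.
#' @export
select_evaluation_points <- function(pop, overrides = NULL) {
  lo <- pop$range$lower; up <- pop$range$upper
  if (!is.null(overrides)) {
    stopifnot(length(overrides) == 2L)
    if (any(overrides < lo | overrides > up)) {
      stop("evaluation point override outside the standardization range [",
           lo, ", ", up, "]", call. = FALSE)
    }
    return(sort(as.numeric(overrides)))
  }
  xmax <- curve_argmax(pop)
  p_low <- lo + 0.25 * (up - lo)
  p_high <- lo + 0.75 * (up - lo)
  if (attr(xmax, "interior")) {
    # ensure the points straddle the interior maximum
    gap <- 0.05 * (up - lo)
    if (p_low >= xmax) p_low <- max(lo, xmax - gap)
    if (p_high <= xmax) p_high <- min(up, xmax + gap)
  } else {
    warning("curve maximum on the range boundary (monotone norm): both ",
            "evaluation points lie on one side", call. = FALSE)
  }
  c(p_low, p_high)
}

#' Derive resilience phenotypes (tangent slopes) for all individuals
#'
#' Evaluates [curve_derivative()] of each individual reaction norm at the two
#' evaluation points. Each individual contributes two phenotypes per norm,
#' expressed in growth change per natural weather unit.
#'
#' @param norms Named list of individual [reaction_norm()]s
#'   (from [individual_reaction_norms()]).
#' @param points Numeric `c(P_low, P_high)` within the standardization range.
#' @return `data.frame` with columns `chicken_id`, `variable`, `statistic`,
#'   `point`, `slope` (g/day per covariate unit).
#' @export
derive_resilience <- function(norms, points) {
  stopifnot(length(points) == 2L)
  one <- norms[[1L]]
  if (any(points < one$range$lower | points > one$range$upper)) {
    stop("evaluation points outside the standardization range", call. = FALSE)
  }
  ids <- names(norms)
  if (is.null(ids)) ids <- as.character(seq_along(norms))
  out <- lapply(points, function(p) {
    data.frame(chicken_id = ids,
               variable = one$variable, statistic = one$statistic,
               point = p,
               slope = vapply(norms, curve_derivative, numeric(1L), x = p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Summary statistics of resilience phenotypes per evaluation point
#'
#' @param phenos Output of [derive_resilience()].
#' @return `data.frame` per (variable, statistic, point): `min`, `max`,
#'   `median`, `mean`, `se` (SD/sqrt(n)), `sd` and `cv_pct`
#'   (100 * SD / |mean|; `NA` with a warning when the mean is zero).
#' @export
summarize_resilience <- function(phenos) {
  sp <- split(phenos, list(phenos$variable, phenos$statistic, phenos$point),
              drop = TRUE)
  out <- lapply(sp, function(d) {
    if (nrow(d) < 2L) stop("need >= 2 individuals per point", call. = FALSE)
    s <- sd(d$slope); m <- mean(d$slope)
    cv <- if (m == 0) {
      warning("mean slope is zero: CV undefined", call. = FALSE)
      NA_real_
    } else 100 * s / abs(m)
    data.frame(variable = d$variable[1L], statistic = d$statistic[1L],
               point = d$point[1L], n = nrow(d),
               min = min(d$slope), max = max(d$slope),
               median = median(d$slope), mean = m,
               se = s / sqrt(nrow(d)), sd = s, cv_pct = cv,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write per-point resilience phenotype files
#'
#' One delimited file per (variable, statistic, point) with columns
#' `chicken_id`, `slope` -- the phenotype input format of [greml()] /
#' [lmm_gwas()] workflows.
#'
#' @param phenos Output of [derive_resilience()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_resilience_phenotypes <- function(phenos, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- split(phenos, list(phenos$variable, phenos$statistic, phenos$point),
              drop = TRUE)
  paths <- vapply(sp, function(d) {
    f <- file.path(dir, sprintf("resilience_%s_%s_P%s.tsv", d$variable[1L],
                                d$statistic[1L], format(d$point[1L])))
    write.table(d[, c("chicken_id", "slope")], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    f
  }, character(1L))
  invisible(unname(paths))
}
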
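#' Read a longitudinal body-weight table
#'
#' Delimited text with header columns `chicken_id,sex,batch,date,weight_g`.
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @return `data.frame` with parsed dates, sorted by chicken and date.
#' @export
read_weight_table <- function(path, sep = ",") {
  w <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("chicken_id", "sex", "batch", "date", "weight_g")
  miss <- setdiff(need, names(w))
  if (length(miss)) {
    stop("weight table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  w$date <- parse_mixed_dates(w$date)
  w[order(w$chicken_id, w$date), , drop = FALSE]
}

#' Derive weekly average daily growth rates
#'
#' For each animal, the growth rate of a week is the live body-weight
#' difference between two consecutive weekly weighings divided by seven
#' (grams/day). Eight weekly weighings therefore yield exactly seven weekly
#' growth records. Weighings separated by more than `interval` days indicate
#' a missed weighing: no rate spans the gap and the gap is flagged.
#'
#' @param weights `data.frame` as from [read_weight_table()].
#' @param interval Expected days between consecutive weighings (default 7;
#'   the divisor of the rate is always 7 days).
#' @return `data.frame` of growth records: `chicken_id`, `batch`, `sex`,
#'   `week_id` (1-based index of the interval within the animal's sequence),
#'   `date` (the later weighing, i.e. the end of the growth week), `growth`
#'   (g/day), `season` and `batch_season` factors. Gap information is
#'   attached as attribute `"gaps"`.
#' @export
#' @examples
#' w <- data.frame(chicken_id = "c1", sex = "F", batch = 1,
#'                 date = as.Date("2020-01-01") + 7 * 0:7,
#'                 weight_g = 500 + 70 * 0:7)
#' compute_growth_rates(w)
compute_growth_rates <- function(weights, interval = 7L) {
  stopifnot(all(c("chicken_id", "date", "weight_g") %in% names(weights)))
  weights$date <- parse_mixed_dates(weights$date)
  weights <- weights[order(weights$chicken_id, weights$date), , drop = FALSE]
  dup <- duplicated(weights[, c("chicken_id", "date")])
  if (any(dup)) {
    stop("duplicate weighing date(s) for chicken(s): ",
         paste(unique(weights$chicken_id[dup]), collapse = ", "), call. = FALSE)
  }
  pieces <- split(weights, weights$chicken_id)
  gaps <- list()
  out <- lapply(pieces, function(d) {
    n <- nrow(d)
    if (n < 2L) return(NULL)
    dd <- as.integer(diff(d$date))
    ok <- dd == interval
    if (any(!ok)) {
      gaps[[as.character(d$chicken_id[1L])]] <<-
        data.frame(chicken_id = d$chicken_id[1L],
                   after = d$date[which(!ok)], days = dd[!ok])
    }
    idx <- which(ok)
    if (!length(idx)) return(NULL)
    data.frame(chicken_id = d$chicken_id[1L],
               batch = if ("batch" %in% names(d)) d$batch[1L] else NA,
               sex = if ("sex" %in% names(d)) d$sex[1L] else NA,
               week_id = idx,
               date = d$date[idx + 1L],
               growth = (d$weight_g[idx + 1L] - d$weight_g[idx]) / 7,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$season <- assign_season(res$date)
  res$batch_season <- factor(paste(res$batch, res$season, sep = ":"))
  if (length(gaps)) {
    warning(length(gaps), " chicken(s) with weighing gaps; no rate spans a gap",
            call. = FALSE)
  }
  attr(res, "gaps") <- if (length(gaps)) do.call(rbind, gaps) else NULL
  res
}

#' Prepare joined growth and weather data for reaction-norm fitting
#'
#' Computes weekly growth records from the weight table, builds 7-day weather
#' windows ending at each batch's weighing dates, aggregates daily weather to
#' weekly means and variances, and joins the two. This is the input of
#' [fit_population_norm()] and [fit_individual_norms()].
#'
#' @param weights Weight table ([read_weight_table()]).
#' @param daily Daily weather table ([read_weather_table()]).
#' @param variables Weather variables to aggregate.
#' @param min_days Passed to [weekly_weather_stats()].
#' @return A list of class `"growth_env_data"` with elements `records`
#'   (growth records), `covariates` (weekly weather statistics keyed by
#'   batch and week-end date) and `tidy` (one row per
#'   chicken-week-variable-statistic).
#' @export
prepare_growth_data <- function(weights, daily,
                                variables = weather_variables,
                                min_days = 5L) {
  records <- compute_growth_rates(weights)
  keys <- unique(records[, c("batch", "date")])
  keys <- keys[order(keys$batch, keys$date), , drop = FALSE]
  cov_list <- lapply(split(keys, keys$batch), function(k) {
    wi <- week_windows(k$date)
    st <- weekly_weather_stats(daily, wi, variables = variables,
                               min_days = min_days)
    st$batch <- k$batch[1L]
    st$date <- k$date[match(st$week_id, wi$week_id)]
    st$week_id <- NULL
    st
  })
  covariates <- do.call(rbind, cov_list)
  rownames(covariates) <- NULL
  tidy <- merge(records, covariates, by = c("batch", "date"), sort = FALSE)
  structure(list(records = records, covariates = covariates, tidy = tidy),
            class = "growth_env_data")
}

#' @export
print.growth_env_data <- function(x, ...) {
  cat("Growth/weather data:", length(unique(x$records$chicken_id)),
      "chickens,", nrow(x$records), "weekly growth records,",
      length(unique(x$covariates$variable)), "weather variables\n")
  invisible(x)
}

# Covariate values matched to each growth record for one (variable, statistic)
# pair; errors listing unmatched (batch, week-end) keys.
match_covariate <- function(data, variable, statistic) {
  stopifnot(inherits(data, "growth_env_data"))
  cv <- data$covariates
  cv <- cv[cv$variable == variable & cv$statistic == statistic, , drop = FALSE]
  if (!nrow(cv)) {
    stop("no weekly covariate for ", variable, " (", statistic, ")",
         call. = FALSE)
  }
  key <- paste(data$records$batch, data$records$date)
  idx <- match(key, paste(cv$batch, cv$date))
  if (anyNA(idx)) {
    stop("growth weeks without a matched weekly covariate: ",
         paste(unique(key[is.na(idx)])[1:min(5, sum(is.na(idx)))],
               collapse = "; "), call. = FALSE)
  }
  cv$value[idx]
}
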
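#' Parse dates in ISO-8601 or DD/MM/YYYY form
#'
#' @param x Character vector (or `Date`, returned unchanged).
#' @return A `Date` vector.
#' @export
parse_mixed_dates <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[dmy] <- as.Date(x[dmy], format = "%d/%m/%Y")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unparseable date(s): ", paste(unique(x[bad])[1:min(5, sum(bad))],
                                        collapse = ", "), call. = FALSE)
  }
  out
}

#' Assign an Ethiopian local season to a date
#'
#' Bega spans October--January, Belg February--May and Kiremt June--September.
#'
#' @param date A `Date` vector (or parseable character, see
#'   [parse_mixed_dates()]).
#' @return Factor with levels `Bega`, `Belg`, `Kiremt`.
#' @export
#' @examples
#' assign_season(as.Date(c("2019-12-18", "2020-07-13", "2021-02-01")))
assign_season <- function(date) {
  date <- parse_mixed_dates(date)
  m <- as.integer(format(date, "%m"))
  out <- character(length(m))
  out[m %in% c(10L, 11L, 12L, 1L)] <- "Bega"
  out[m %in% 2:5] <- "Belg"
  out[m %in% 6:9] <- "Kiremt"
  factor(out, levels = c("Bega", "Belg", "Kiremt"))
}

weather_variables <- c("tmax", "tmin", "tavg", "rh", "thi", "precip")

#' Read a daily weather table
#'
#' Expects delimited text with header columns
#' `date,tmax,tmin,tavg,rh,precip` (temperatures in degrees C, relative
#' humidity in percent, precipitation in mm). A daily THI column is added via
#' [compute_thi()]. Basic physical invariants are validated.
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @param thi [thi_params()] used for the added THI column.
#' @return `data.frame` with columns `date`, `tmax`, `tmin`, `tavg`, `rh`,
#'   `precip`, `thi` and `season`.
#' @export
read_weather_table <- function(path, sep = ",", thi = thi_params()) {
  w <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("date", "tmax", "tmin", "tavg", "rh", "precip")
  miss <- setdiff(need, names(w))
  if (length(miss)) {
    stop("weather table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  w$date <- parse_mixed_dates(w$date)
  validate_weather(w)
  w$thi <- compute_thi(w$tavg, w$rh, thi)
  w$season <- assign_season(w$date)
  w[order(w$date), , drop = FALSE]
}

validate_weather <- function(w) {
  with(w, {
    ok <- is.na(tmin) | is.na(tavg) | is.na(tmax) | (tmin <= tavg & tavg <= tmax)
    if (any(!ok)) {
      stop("weather records violating tmin <= tavg <= tmax on: ",
           paste(format(date[!ok])[1:min(5, sum(!ok))], collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.na(rh) & (rh < 0 | rh > 100))) {
      stop("relative humidity outside [0, 100]", call. = FALSE)
    }
    if (any(!is.na(precip) & precip < 0)) {
      stop("negative precipitation", call. = FALSE)
    }
  })
  invisible(w)
}

#' Build 7-day weather windows ending at weighing dates
#'
#' Growth accrued over the interval between two consecutive weighings is
#' paired with weather over the 7 days ending on the day of the later
#' weighing.
#'
#' @param end_dates `Date` vector of window end dates (weighing dates).
#' @param week_id Optional integer ids (default `seq_along(end_dates)`).
#' @return `data.frame` with `week_id`, `start`, `end` (both inclusive,
#'   7 calendar days).
#' @export
week_windows <- function(end_dates, week_id = seq_along(end_dates)) {
  end_dates <- parse_mixed_dates(end_dates)
  data.frame(week_id = as.integer(week_id),
             start = end_dates - 6L,
             end = end_dates)
}

#' Weekly means and variances of daily weather values
#'
#' For each 7-day window and each weather variable (including daily THI),
#' computes the arithmetic mean and the sample variance (n-1 denominator) of
#' the daily values. Windows with some missing days are computed on the
#' available days when at least `min_days` are present (and flagged
#' `incomplete`); windows with fewer days are dropped with a flag. Empty
#' windows are an error.
#'
#' @param daily Daily weather `data.frame` as from [read_weather_table()]
#'   (a `thi` column is added if absent).
#' @param windows Window `data.frame` from [week_windows()].
#' @param variables Weather variables to aggregate.
#' @param min_days Minimum daily values required to keep a window (default 5).
#' @return `data.frame` with columns `week_id`, `variable`, `statistic`
#'   (`"mean"`/`"variance"`), `value`, `n_days`, `incomplete`. Dropped
#'   windows are reported via a warning and an attribute `"dropped"`.
#' @export
#' @examples
#' d <- data.frame(date = as.Date("2020-01-01") + 0:6, tmax = 20 + 1:7,
#'                 tmin = 5, tavg = 12.5 + 1:7 / 2, rh = 50, precip = 0)
#' weekly_weather_stats(d, week_windows(as.Date("2020-01-07")))
weekly_weather_stats <- function(daily, windows,
                                 variables = weather_variables,
                                 min_days = 5L) {
  if (!"thi" %in% names(daily) && all(c("tavg", "rh") %in% names(daily))) {
    daily$thi <- compute_thi(daily$tavg, daily$rh)
  }
  variables <- intersect(variables, names(daily))
  daily$date <- parse_mixed_dates(daily$date)
  out <- vector("list", nrow(windows))
  dropped <- integer(0)
  for (i in seq_len(nrow(windows))) {
    span <- seq(windows$start[i], windows$end[i], by = "day")
    if (length(span) != 7L) {
      stop("window ", windows$week_id[i], " does not span 7 days", call. = FALSE)
    }
    rows <- daily[daily$date %in% span, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("no daily weather for window ending ", format(windows$end[i]),
           call. = FALSE)
    }
    per_var <- lapply(variables, function(v) {
      x <- rows[[v]][!is.na(rows[[v]])]
      n <- length(x)
      data.frame(week_id = windows$week_id[i],
                 variable = v,
                 statistic = c("mean", "variance"),
                 value = if (n == 0L) c(NA_real_, NA_real_) else
                   c(mean(x), if (n >= 2L) stats::var(x) else NA_real_),
                 n_days = n,
                 incomplete = n < 7L,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, per_var)
    if (any(res$n_days < min_days)) {
      dropped <- c(dropped, windows$week_id[i])
      next
    }
    out[[i]] <- res
  }
  if (length(dropped)) {
    warning("dropped window(s) with fewer than ", min_days, " daily values: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(week_id = integer(0), variable = character(0),
                      statistic = character(0), value = numeric(0),
                      n_days = integer(0), incomplete = logical(0))
  }
  if (any(res$incomplete)) {
    warning("some windows computed on fewer than 7 daily values (flagged)",
            call. = FALSE)
  }
  attr(res, "dropped") <- dropped
  res
}
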
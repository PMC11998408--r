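test_that("THI reproduces the pivot/saturation identities and hand values", {
  expect_equal(compute_thi(14.4, 30), 14.4)
  expect_equal(compute_thi(20, 100), 20)
  expect_equal(compute_thi(20, 50), 19.132)
  # vectorised
  expect_equal(compute_thi(c(14.4, 20), c(30, 100)), c(14.4, 20))
})

test_that("THI validates humidity and pivot ranges", {
  expect_error(compute_thi(20, 120), "humidity")
  expect_error(compute_thi(20, -1), "humidity")
  expect_error(thi_params(pivot_temp = 50), "pivot_temp")
})

test_that("THI is monotone in humidity with sign flipping at the pivot", {
  rh <- seq(0, 100, by = 5)
  above <- compute_thi(rep(25, length(rh)), rh)   # hot: humid feels hotter
  below <- compute_thi(rep(5, length(rh)), rh)    # cold: humid feels colder
  expect_true(all(diff(above) >= 0))
  expect_true(all(diff(below) <= 0))
  at_pivot <- compute_thi(rep(14.4, length(rh)), rh)
  expect_equal(at_pivot, rep(14.4, length(rh)))
})

test_that("local seasons follow the Bega/Belg/Kiremt month mapping", {
  expect_equal(as.character(assign_season(as.Date("2019-12-18"))), "Bega")
  expect_equal(as.character(assign_season(as.Date("2020-07-13"))), "Kiremt")
  expect_equal(as.character(assign_season(as.Date("2021-02-01"))), "Belg")
  # all twelve months
  m <- assign_season(as.Date(sprintf("2020-%02d-15", 1:12)))
  expect_equal(as.character(m),
               c("Bega", rep("Belg", 4), rep("Kiremt", 4), rep("Bega", 3)))
})

test_that("dates parse in ISO and DD/MM/YYYY forms", {
  expect_equal(parse_mixed_dates(c("2020-01-31", "31/01/2020")),
               rep(as.Date("2020-01-31"), 2))
  expect_error(parse_mixed_dates("01-31-2020"), "unparseable")
})

test_that("weekly stats give exact closed-form mean/variance", {
  d <- daily_weather(tavg = 16)
  st <- weekly_weather_stats(d, week_windows(max(d$date)),
                             variables = "tavg")
  expect_equal(st$value[st$statistic == "mean"], 16)
  expect_equal(st$value[st$statistic == "variance"], 0)

  d2 <- daily_weather()
  d2$tavg <- 1:7
  d2$tmax <- 40  # keep tmin <= tavg <= tmax invariant satisfied
  d2$tmin <- 0
  st2 <- weekly_weather_stats(d2, week_windows(max(d2$date)),
                              variables = "tavg")
  expect_equal(st2$value[st2$statistic == "mean"], 4)
  expect_equal(st2$value[st2$statistic == "variance"], 28 / 6)
})

test_that("weekly stats agree with an independent two-pass oracle", {
  set.seed(99)
  d <- daily_weather()
  d$tavg <- rnorm(7, 16, 3)
  d$tmax <- d$tavg + runif(7, 1, 5)
  d$tmin <- d$tavg - runif(7, 1, 5)
  d$rh <- runif(7, 20, 90)
  d$precip <- rexp(7)
  st <- weekly_weather_stats(d, week_windows(max(d$date)),
                             variables = c("tavg", "rh", "precip"))
  two_pass <- function(x) {
    m <- sum(x) / length(x)
    list(mean = m, variance = sum((x - m)^2) / (length(x) - 1))
  }
  for (v in c("tavg", "rh", "precip")) {
    o <- two_pass(d[[v]])
    expect_equal(st$value[st$variable == v & st$statistic == "mean"], o$mean)
    expect_equal(st$value[st$variable == v & st$statistic == "variance"],
                 o$variance)
  }
})

test_that("weekly variance is nonnegative and zero iff constant", {
  set.seed(11)
  for (r in 1:20) {
    d <- daily_weather()
    d$tavg <- if (r %% 2) rep(round(rnorm(1, 16), 3), 7) else rnorm(7, 16, 2)
    d$tmax <- 40; d$tmin <- -10
    st <- weekly_weather_stats(d, week_windows(max(d$date)),
                               variables = "tavg")
    v <- st$value[st$statistic == "variance"]
    expect_gte(v, 0)
    expect_identical(v == 0, length(unique(d$tavg)) == 1L)
  }
})

test_that("missing-day windows are flagged, small windows dropped, empty error", {
  d <- daily_weather()
  expect_warning(
    weekly_weather_stats(d[-c(1, 2), ], week_windows(max(d$date)),
                         variables = "tavg"),
    "fewer than 7")
  st <- suppressWarnings(
    weekly_weather_stats(d[-c(1, 2), ], week_windows(max(d$date)),
                         variables = "tavg"))
  expect_true(all(st$incomplete))
  expect_equal(unique(st$n_days), 5L)
  # fewer than 5 days -> dropped with warning
  expect_warning(
    weekly_weather_stats(d[1:3, ], week_windows(max(d$date)),
                         variables = "tavg"),
    "dropped")
  st2 <- suppressWarnings(
    weekly_weather_stats(d[1:3, ], week_windows(max(d$date)),
                         variables = "tavg"))
  expect_equal(nrow(st2), 0L)
  expect_equal(attr(st2, "dropped"), 1L)
  expect_error(
    suppressWarnings(weekly_weather_stats(
      d, week_windows(as.Date("2021-01-07")), variables = "tavg")),
    "no daily weather")
})

test_that("weather reader validates physical invariants and adds THI", {
  d <- daily_weather()
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  w <- read_weather_table(f)
  expect_equal(w$thi, compute_thi(d$tavg, d$rh))
  expect_s3_class(w$season, "factor")
  d_bad <- d; d_bad$tmin[3] <- 50
  write.csv(d_bad, f, row.names = FALSE)
  expect_error(read_weather_table(f), "tmin <= tavg <= tmax")
})
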
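# Shared fixture builders. Everything is generated in code at test time.

# one week of daily weather, optionally with explicit values
daily_weather <- function(start = as.Date("2020-01-01"), n = 7,
                          tavg = 16, spread = 5, rh = 50, precip = 0) {
  data.frame(date = start + 0:(n - 1),
             tmax = rep_len(tavg + spread, n), tmin = rep_len(tavg - spread, n),
             tavg = rep_len(tavg, n), rh = rep_len(rh, n),
             precip = rep_len(precip, n))
}

# small toy genotype matrix with deterministic content
toy_genotypes <- function(n = 12, m = 30, seed = 42, missing_rate = 0,
                          chr = NULL) {
  set.seed(seed)
  p <- runif(m, 0.05, 0.5)
  dos <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  if (missing_rate > 0) {
    dos[runif(n * m) < missing_rate] <- NA
  }
  if (is.null(chr)) chr <- rep("1", m)
  pos <- integer(m)
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    pos[idx] <- sort(sample.int(1e6, length(idx)))
  }
  genotype_matrix(dos, sprintf("s%03d", seq_len(n)),
                  data.frame(chr = chr, id = sprintf("m%03d", seq_len(m)),
                             pos = pos, a1 = "A", a2 = "B",
                             stringsAsFactors = FALSE))
}

# balanced two-batch growth dataset simulated outside the generator, for
# direct control over the covariate values in small model tests
tiny_growth_data <- function(n_per_batch = 30, seed = 1, a = c(10, 2, -1),
                             sd_int = 1, sd_res = 0.5) {
  set.seed(seed)
  starts <- as.Date(c("2020-01-08", "2020-07-08"))
  cfg_x <- list(seq(14, 17, length.out = 7), seq(14.5, 17.5, length.out = 7))
  rng <- standardization_range(14, 17.5)
  rows <- list()
  for (b in 1:2) {
    xs <- standardize(cfg_x[[b]], rng, warn = FALSE)
    Phi <- legendre_row(xs)
    pop <- drop(Phi %*% a)
    for (i in seq_len(n_per_batch)) {
      id <- sprintf("b%dc%02d", b, i)
      sex <- if (i %% 2) "F" else "M"
      u <- rnorm(1, 0, sd_int)
      growth <- pop + (sex == "M") * 0.5 + u + rnorm(7, 0, sd_res)
      w <- 500 + cumsum(c(0, growth * 7))
      rows[[id]] <- data.frame(chicken_id = id, sex = sex, batch = b,
                               date = starts[b] + 7 * 0:7, weight_g = w)
    }
  }
  weights <- do.call(rbind, rows)
  weather <- do.call(rbind, lapply(1:2, function(b) {
    dates <- seq(starts[b] - 6, starts[b] + 7 * 7, by = "day")
    # daily tavg constant within each 7-day window so the weekly means
    # equal cfg_x exactly
    wk <- ceiling(as.numeric(dates - starts[b]) / 7)
    wk[wk < 1] <- 1; wk[wk > 7] <- 7
    data.frame(date = dates, tmax = 30, tmin = 5,
               tavg = cfg_x[[b]][wk], rh = 50, precip = 0)
  }))
  list(weights = weights, weather = weather, range = rng, a = a)
}
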
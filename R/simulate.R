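#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study conditions the package targets: about 1,590
#' chickens reared in 4 batches starting in different local seasons, 8
#' weekly weighings each (7 weekly growth rates), Addis-Ababa-like highland
#' weather across the Bega/Belg/Kiremt seasons, and a desk-scale SNP panel.
#' The true population norm defaults to the weekly-mean THI norm scale, and
#' the deviation covariance to the observed deviation spread of that trait.
#'
#' @param seed Integer seed; all generator output is a pure function of the
#'   config (including this seed).
#' @param n_chickens Total chickens (default 1590, split across batches).
#' @param batch_sizes Chickens per batch (default proportional to the
#'   4-batch design; recycled/truncated to sum to `n_chickens`).
#' @param batch_starts First weighing date per batch.
#' @param weighings Weighings per chicken (default 8).
#' @param season Per-season weather parameters (list of lists with `tavg`,
#'   `spread_hi`, `spread_lo`, `rh`, `rain_prob`, `rain_mean`).
#' @param tavg_sd,rh_sd Daily AR(1) noise SDs; `ar` the AR coefficient.
#' @param driver_variable,driver_statistic Weekly covariate driving growth.
#' @param true_norm Length-3 true population-norm coefficients (plain basis).
#' @param sex_effect,batch_effect_sd Fixed-effect sizes (g/day).
#' @param Sigma_a True 3 x 3 deviation covariance.
#' @param h2_dev Heritable fraction of each deviation coefficient (and hence
#'   of any slope phenotype), in `[0, 1]`.
#' @param residual_sd Residual SD of weekly growth (g/day).
#' @param start_weight_mean,start_weight_sd Body weight at first weighing (g).
#' @param n_snps,n_chrom,maf_range SNP panel size, autosome count and
#'   allele-frequency range.
#' @param n_causal Causal SNPs per genetic factor.
#' @param divergence Allele-frequency divergence between two subpopulations
#'   (0 = unstructured).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chickens = 1590L,
                       batch_sizes = NULL,
                       batch_starts = as.Date(c("2019-12-18", "2020-07-13",
                                                "2020-10-14", "2020-12-24")),
                       weighings = 8L,
                       season = list(
                         Bega = list(tavg = 16.1, spread_hi = 7.4,
                                     spread_lo = 6.6, rh = 59,
                                     rain_prob = 0.10, rain_mean = 3.5),
                         Belg = list(tavg = 17.3, spread_hi = 8.2,
                                     spread_lo = 6.4, rh = 55,
                                     rain_prob = 0.10, rain_mean = 2.5),
                         Kiremt = list(tavg = 16.2, spread_hi = 4.9,
                                       spread_lo = 3.3, rh = 83,
                                       rain_prob = 0.80, rain_mean = 12)),
                       tavg_sd = 0.8, rh_sd = 4, ar = 0.5,
                       driver_variable = "thi", driver_statistic = "mean",
                       true_norm = c(13.27, 1.78, -0.31),
                       sex_effect = 0.8, batch_effect_sd = 0.5,
                       Sigma_a = NULL,
                       h2_dev = 0.2,
                       residual_sd = 2,
                       start_weight_mean = 500, start_weight_sd = 50,
                       n_snps = 5000L, n_chrom = 5L,
                       maf_range = c(0.02, 0.5),
                       n_causal = 100L,
                       divergence = 0) {
  if (is.null(batch_sizes)) {
    prop <- c(436, 429, 406, 315) / 1586
    batch_sizes <- round(prop * n_chickens)
    batch_sizes[1L] <- n_chickens - sum(batch_sizes[-1L])
  }
  stopifnot(sum(batch_sizes) == n_chickens,
            length(batch_sizes) == length(batch_starts),
            h2_dev >= 0, h2_dev <= 1, residual_sd >= 0)
  if (is.null(Sigma_a)) {
    sds <- c(1.58, 0.055, 0.38)
    corr <- matrix(c(1, -0.72, 0.62,
                     -0.72, 1, -0.45,
                     0.62, -0.45, 1), 3L, 3L)
    Sigma_a <- diag(sds) %*% corr %*% diag(sds)
  }
  stopifnot(all(eigen(Sigma_a, symmetric = TRUE,
                      only.values = TRUE)$values > -1e-10))
  structure(list(seed = as.integer(seed), n_chickens = as.integer(n_chickens),
                 batch_sizes = as.integer(batch_sizes),
                 batch_starts = as.Date(batch_starts),
                 weighings = as.integer(weighings), season = season,
                 tavg_sd = tavg_sd, rh_sd = rh_sd, ar = ar,
                 driver_variable = driver_variable,
                 driver_statistic = driver_statistic,
                 true_norm = true_norm, sex_effect = sex_effect,
                 batch_effect_sd = batch_effect_sd, Sigma_a = Sigma_a,
                 h2_dev = h2_dev, residual_sd = residual_sd,
                 start_weight_mean = start_weight_mean,
                 start_weight_sd = start_weight_sd,
                 n_snps = as.integer(n_snps), n_chrom = as.integer(n_chrom),
                 maf_range = maf_range, n_causal = as.integer(n_causal),
                 divergence = divergence),
            class = "sim_config")
}

#' Simulate a daily weather series
#'
#' Seasonal mean plus AR(1) daily noise for average temperature, with
#' season-specific diurnal spreads giving tmax/tmin; humidity as a seasonal
#' level plus AR(1) noise bounded to `[0, 100]`; precipitation zero-inflated
#' gamma with wet-season intensity. Deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @param from,to Date range (default: spanning all batch windows with a
#'   margin).
#' @return Daily weather `data.frame` in the format of
#'   [read_weather_table()].
#' @export
simulate_weather <- function(cfg, from = NULL, to = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(from)) from <- min(cfg$batch_starts) - 14L
  if (is.null(to)) to <- max(cfg$batch_starts) + 7L * cfg$weighings + 14L
  set.seed(cfg$seed + 11L)
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  nd <- length(dates)
  season <- as.character(assign_season(dates))
  par <- cfg$season
  get <- function(field) vapply(season, function(s) par[[s]][[field]],
                                numeric(1L))
  ar_noise <- function(sd) {
    z <- rnorm(nd, 0, sd)
    if (sd == 0) return(z)
    x <- numeric(nd)
    x[1L] <- z[1L]
    for (i in 2:nd) x[i] <- cfg$ar * x[i - 1L] + sqrt(1 - cfg$ar^2) * z[i]
    x
  }
  tavg <- get("tavg") + ar_noise(cfg$tavg_sd)
  tmax <- tavg + pmax(0.5, get("spread_hi") + ar_noise(cfg$tavg_sd))
  tmin <- tavg - pmax(0.5, get("spread_lo") + ar_noise(cfg$tavg_sd))
  rh <- pmin(100, pmax(0, get("rh") + ar_noise(cfg$rh_sd)))
  wet <- runif(nd) < get("rain_prob")
  precip <- ifelse(wet, rgamma(nd, shape = 1.2,
                               scale = get("rain_mean") / 1.2), 0)
  data.frame(date = dates, tmax = tmax, tmin = tmin, tavg = tavg, rh = rh,
             precip = precip)
}

#' Simulate a SNP genotype panel
#'
#' Allele frequencies are drawn uniformly on `maf_range`; dosages are
#' binomial(2, p) independently per sample. With `divergence > 0` the
#' samples split into two equal subpopulations whose frequencies differ by
#' `2 * divergence` per SNP (for population-structure tests).
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] with samples `chk0001`, ... The per-SNP
#'   truth frequencies are attached as attribute `"freq"`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 23L)
  n <- cfg$n_chickens; m <- cfg$n_snps
  p <- runif(m, cfg$maf_range[1L], cfg$maf_range[2L])
  ids <- sprintf("chk%04d", seq_len(n))
  if (cfg$divergence > 0) {
    half <- n %/% 2L
    p1 <- pmin(0.99, pmax(0.01, p + cfg$divergence))
    p2 <- pmin(0.99, pmax(0.01, p - cfg$divergence))
    d1 <- matrix(rbinom(half * m, 2L, rep(p1, each = half)), half, m)
    d2 <- matrix(rbinom((n - half) * m, 2L, rep(p2, each = n - half)),
                 n - half, m)
    dos <- rbind(d1, d2)
  } else {
    dos <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  }
  # contiguous chromosome blocks with sorted positions, so SNP k of the
  # dosage matrix is row k of the map
  sizes <- diff(floor(seq(0L, m, length.out = cfg$n_chrom + 1L)))
  chr <- rep(as.character(seq_len(cfg$n_chrom)), times = sizes)
  pos <- unlist(lapply(sizes, function(s) sort(sample.int(1e8, s))),
                use.names = FALSE)
  snps <- data.frame(chr = chr, id = sprintf("snp%05d", seq_len(m)),
                     pos = pos, a1 = "A", a2 = "B",
                     stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, ids, snps)
  attr(g, "freq") <- p
  g
}

#' Simulate weekly weighings with a known reaction-norm architecture
#'
#' Weekly growth for chicken i in week j is built as
#' `sex + batch_season + popnorm(x_j) + phi(x_j) . a_i + e_ij`, where `x_j`
#' is the batch's weekly driver covariate (computed from the simulated
#' weather exactly as the analysis pipeline computes it), `a_i` the
#' chicken's deviation triple and `e_ij` Gaussian residual. Deviations are
#' the sum of a genetic part (three independent standardized polygenic
#' scores from disjoint causal SNP sets, scaled to the target heritable
#' fraction) and an environmental part, with total covariance `Sigma_a`;
#' every linear function of the deviations then has heritability `h2_dev`
#' by construction. Body weights are integrated from a starting weight at
#' the first weighing, so [compute_growth_rates()] inverts the construction
#' exactly (weights are stored unrounded).
#'
#' @param cfg A [sim_config()].
#' @param weather Daily weather from [simulate_weather()].
#' @param genotypes A [genotype_matrix()] from [simulate_genotypes()]
#'   (or `NULL` for a purely environmental simulation).
#' @return List of class `"sim_growth"`: `weights` (weight table in
#'   [read_weight_table()] format) and `truth` (deviations, genetic scores,
#'   causal effects, true norm and range, fixed effects, per-week covariate
#'   values).
#' @export
simulate_growth <- function(cfg, weather, genotypes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 37L)
  n <- cfg$n_chickens
  nb <- length(cfg$batch_sizes)
  batch <- rep(seq_len(nb), cfg$batch_sizes)
  ids <- sprintf("chk%04d", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  # weekly driver covariate per batch, computed as the pipeline computes it
  cov_by_batch <- lapply(seq_len(nb), function(b) {
    ends <- cfg$batch_starts[b] + 7L * seq_len(cfg$weighings - 1L)
    st <- weekly_weather_stats(weather, week_windows(ends),
                               variables = cfg$driver_variable)
    st$value[st$statistic == cfg$driver_statistic]
  })
  xall <- unlist(cov_by_batch)
  rng <- standardization_range(min(xall), max(xall))
  pop <- reaction_norm(cfg$true_norm, rng, variable = cfg$driver_variable,
                       statistic = cfg$driver_statistic)
  # deviations: genetic + environmental, total covariance Sigma_a
  h2 <- cfg$h2_dev
  gscore <- matrix(0, n, 3L)
  causal <- NULL
  if (h2 > 0) {
    if (is.null(genotypes)) {
      stop("h2_dev > 0 requires genotypes", call. = FALSE)
    }
    m <- ncol(genotypes$dosage)
    if (3L * cfg$n_causal > m) {
      stop("more causal SNPs requested than available (3 x ", cfg$n_causal,
           " > ", m, ")", call. = FALSE)
    }
    pick <- sample.int(m, 3L * cfg$n_causal)
    causal <- lapply(1:3, function(k) {
      idx <- sort(pick[((k - 1L) * cfg$n_causal + 1L):(k * cfg$n_causal)])
      eff <- rnorm(cfg$n_causal)
      s <- drop(impute_dosage(subset_genotypes(genotypes, snps = idx)) %*% eff)
      list(snps = genotypes$snps$id[idx], effects = eff,
           score = (s - mean(s)) / sd(s))
    })
    gscore <- vapply(causal, `[[`, numeric(n), "score")
  }
  eg <- eigen(cfg$Sigma_a, symmetric = TRUE)
  L <- diag(sqrt(pmax(eg$values, 0)), 3L) %*% t(eg$vectors)
  zenv <- matrix(rnorm(n * 3L), n, 3L)
  dev <- (sqrt(h2) * gscore + sqrt(1 - h2) * zenv) %*% L
  rownames(dev) <- ids
  colnames(dev) <- c("a0", "a1", "a2")
  # reference batch carries zero effect so the true population-norm
  # intercept stays identifiable under reference-level coding
  batch_eff <- c(0, rnorm(nb - 1L, 0, cfg$batch_effect_sd))
  rows <- vector("list", nb)
  truth_weeks <- vector("list", nb)
  for (b in seq_len(nb)) {
    in_b <- which(batch == b)
    nwk <- cfg$weighings - 1L
    x <- cov_by_batch[[b]]
    xs <- standardize(x, rng, warn = FALSE)
    Phi <- legendre_row(xs)
    popval <- drop(Phi %*% pop$coef)
    fixed <- ifelse(sex[in_b] == "M", cfg$sex_effect, 0) + batch_eff[b]
    growth <- outer(fixed, popval, "+") + dev[in_b, , drop = FALSE] %*% t(Phi) +
      matrix(rnorm(length(in_b) * nwk, 0, cfg$residual_sd),
             length(in_b), nwk)
    w0 <- rnorm(length(in_b), cfg$start_weight_mean, cfg$start_weight_sd)
    wts <- cbind(w0, w0 + t(apply(growth * 7, 1L, cumsum)))
    dates <- cfg$batch_starts[b] + 7L * (0:(cfg$weighings - 1L))
    rows[[b]] <- data.frame(
      chicken_id = rep(ids[in_b], each = cfg$weighings),
      sex = rep(sex[in_b], each = cfg$weighings),
      batch = b,
      date = rep(dates, times = length(in_b)),
      weight_g = as.vector(t(wts)),
      stringsAsFactors = FALSE)
    truth_weeks[[b]] <- data.frame(batch = b, date = dates[-1L],
                                   covariate = x, pop_value = popval)
  }
  weights <- do.call(rbind, rows)
  truth <- list(deviations = dev, genetic_scores = gscore, causal = causal,
                pop_norm = pop, range = rng, sex_effect = cfg$sex_effect,
                batch_effects = batch_eff, sex = setNames(sex, ids),
                batch = setNames(batch, ids),
                weeks = do.call(rbind, truth_weeks))
  structure(list(weights = weights, truth = truth, config = cfg),
            class = "sim_growth")
}

#' Simulate a polygenic phenotype at a target heritability
#'
#' `y = sqrt(h2) * s + sqrt(1 - h2) * e` with `s` a standardized polygenic
#' score over `n_causal` random SNPs and `e` standard normal: phenotypic
#' variance 1, genetic variance `h2`.
#'
#' @param g A [genotype_matrix()].
#' @param h2 Target heritability in `[0, 1]`.
#' @param n_causal Number of causal SNPs.
#' @param seed Integer seed.
#' @return Named phenotype vector with attribute `"causal"`.
#' @export
simulate_polygenic_phenotype <- function(g, h2, n_causal = 100L, seed = 1L) {
  stopifnot(h2 >= 0, h2 <= 1)
  set.seed(seed)
  n <- length(g$samples)
  s <- rep(0, n)
  idx <- integer(0)
  if (h2 > 0) {
    idx <- sort(sample.int(ncol(g$dosage), n_causal))
    eff <- rnorm(n_causal)
    s <- drop(impute_dosage(subset_genotypes(g, snps = idx)) %*% eff)
    s <- (s - mean(s)) / sd(s)
  }
  y <- sqrt(h2) * s + sqrt(1 - h2) * rnorm(n)
  names(y) <- g$samples
  attr(y, "causal") <- g$snps$id[idx]
  y
}

#' Write simulated data in the pipeline's input formats
#'
#' @param sim A `"sim_growth"` object.
#' @param weather Matching daily weather table.
#' @param genotypes Optional [genotype_matrix()] (written as PLINK trio).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, weather, genotypes = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pw <- file.path(dir, "weather.csv")
  write.table(weather, pw, sep = ",", quote = FALSE, row.names = FALSE)
  pg <- file.path(dir, "weights.csv")
  write.table(sim$weights, pg, sep = ",", quote = FALSE, row.names = FALSE)
  paths <- c(pw, pg)
  if (!is.null(genotypes)) {
    write_plink(genotypes, file.path(dir, "genotypes"))
    paths <- c(paths, file.path(dir, "genotypes.bed"))
  }
  tr <- file.path(dir, "truth.tsv")
  dv <- as.data.frame(sim$truth$deviations)
  dv$chicken_id <- rownames(sim$truth$deviations)
  write.table(dv[, c("chicken_id", "a0", "a1", "a2")], tr, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(paths, tr))
}
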
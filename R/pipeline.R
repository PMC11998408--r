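#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list; a user YAML file
#' is merged over these defaults by [run_pipeline()]. All QC thresholds ship
#' at the package's standard values (sample call rate 0.90, MAF 0.02,
#' LD r-squared 0.8, IBS 0.98, annotation window 200 kb, alpha 0.05).
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_chickens = 300L, n_snps = 1000L,
                    h2_dev = 0.2, n_causal = NULL),
    inputs = list(weather = NULL, weights = NULL, genotypes = NULL,
                  genotype_format = "plink", annotation = NULL),
    norms = list(pairs = list(list(variable = "thi", statistic = "mean")),
                 normalized = FALSE, tol = 1e-8, max_iter = 1000L),
    resilience = list(use_default_points = TRUE),
    qc = list(sample_call_rate = 0.90, snp_maf = 0.02, ld_r2 = 0.8,
              ibs = 0.98, ld_prune = FALSE),
    gwas = list(mode = "approx", alpha = 0.05, run = TRUE,
                annotation_window = 200000L),
    out_dir = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: data simulation (optional), data
#' preparation, reaction-norm fitting, resilience-phenotype derivation, and
#' genomic analysis (QC, GRM, PCA, GREML, GWAS, optional annotation). Every
#' stage writes delimited outputs into the run directory and the run closes
#' with a manifest (package version, seed, config hash, per-output row
#' counts and checksums). Reruns with identical config and inputs are
#' bit-identical. A stage failure aborts the run with the stage name;
#' outputs of the failed stage are retained with a `.partial` suffix.
#'
#' @param config Path to a YAML configuration file, or a nested list merged
#'   over [default_pipeline_config()].
#' @param out_dir Run directory (default from config; required).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(default_pipeline_config(), cfg)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("an output directory is required",
                                 call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = as.character(packageVersion("resilnorm")),
                   seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   stages = list())
  written <- character(0)
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      fresh <- setdiff(list.files(cfg$out_dir, full.names = TRUE), written)
      if (length(fresh)) file.rename(fresh, paste0(fresh, ".partial"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    written <<- list.files(cfg$out_dir, full.names = TRUE)
    message(sprintf("[%s] stage %s done (%.1fs)",
                    format(Sys.time(), "%H:%M:%S"), name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  sim <- NULL; genotypes <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sim <- stage("simulate", function() {
      nc <- cfg$simulate$n_causal
      if (is.null(nc)) nc <- max(1L, min(100L, cfg$simulate$n_snps %/% 10L))
      sc <- sim_config(seed = cfg$seed,
                       n_chickens = cfg$simulate$n_chickens,
                       n_snps = cfg$simulate$n_snps,
                       h2_dev = cfg$simulate$h2_dev,
                       n_causal = nc)
      weather <- simulate_weather(sc)
      genotypes <- simulate_genotypes(sc)
      growth <- simulate_growth(sc, weather, genotypes)
      write_simulation(growth, weather, genotypes, cfg$out_dir)
      list(weather = weather, growth = growth, genotypes = genotypes)
    })
    cfg$inputs$weather <- file.path(cfg$out_dir, "weather.csv")
    cfg$inputs$weights <- file.path(cfg$out_dir, "weights.csv")
    genotypes <- sim$genotypes
  }

  prep <- stage("dataprep", function() {
    weather <- read_weather_table(cfg$inputs$weather)
    weights <- read_weight_table(cfg$inputs$weights)
    pr <- prepare_growth_data(weights, weather)
    write.table(pr$tidy, file.path(cfg$out_dir, "growth_env.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pr
  })

  fits <- stage("norms", function() {
    lapply(cfg$norms$pairs, function(pr2) {
      fit2 <- fit_individual_norms(prep, pr2$variable, pr2$statistic,
                                   normalized = isTRUE(cfg$norms$normalized),
                                   tol = cfg$norms$tol,
                                   max_iter = cfg$norms$max_iter)
      fit2
    })
  })
  stage("norm-tables", function() {
    write.table(population_norm_table(fits),
                file.path(cfg$out_dir, "population_norms.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    devsum <- do.call(rbind, lapply(fits, function(f)
      cbind(variable = f$variable, statistic = f$statistic, summary(f))))
    write.table(devsum, file.path(cfg$out_dir, "deviation_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cors <- do.call(rbind, lapply(fits, function(f)
      cbind(variable = f$variable, statistic = f$statistic,
            coeff_correlations(f))))
    write.table(cors, file.path(cfg$out_dir, "deviation_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    NULL
  })

  phenos <- stage("resilience", function() {
    defaults <- resilience_point_defaults()
    all <- lapply(fits, function(f) {
      norms <- individual_reaction_norms(f$norm, f)
      ov <- NULL
      if (isTRUE(cfg$resilience$use_default_points)) {
        row <- defaults[defaults$variable == f$variable &
                          defaults$statistic == f$statistic, ]
        if (nrow(row) == 1L &&
            row$P_low >= f$norm$range$lower &&
            row$P_high <= f$norm$range$upper) {
          ov <- c(row$P_low, row$P_high)
        }
      }
      pts <- select_evaluation_points(f$norm, overrides = ov)
      derive_resilience(norms, pts)
    })
    ph <- do.call(rbind, all)
    write_resilience_phenotypes(ph, cfg$out_dir)
    write.table(summarize_resilience(ph),
                file.path(cfg$out_dir, "resilience_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ph
  })

  if (is.null(genotypes) && !is.null(cfg$inputs$genotypes)) {
    genotypes <- stage("genotype-input", function() {
      if (identical(cfg$inputs$genotype_format, "vcf")) {
        read_vcf_genotypes(cfg$inputs$genotypes)
      } else {
        read_plink(cfg$inputs$genotypes)
      }
    })
  }

  if (!is.null(genotypes)) {
    gen <- stage("genomics", function() {
      g <- qc_filter(genotypes, cfg$qc$sample_call_rate, cfg$qc$snp_maf)
      invisible(utils::capture.output(
        print_qc_report(g, file.path(cfg$out_dir, "qc_report.txt"))))
      dup <- ibs_duplicates(g, cfg$qc$ibs)
      if (nrow(dup)) {
        g <- subset_genotypes(
          g, samples = setdiff(g$samples, unique(dup$remove)))
      }
      if (isTRUE(cfg$qc$ld_prune)) {
        kept <- ld_prune(g, r2_max = cfg$qc$ld_r2)
        g <- subset_genotypes(g, snps = attr(kept, "index"))
      }
      grm <- compute_grm(g)
      write_grm(grm, file.path(cfg$out_dir, "grm"))
      pcs <- genotype_pca(grm, k = 3L)
      list(g = g, grm = grm, pcs = pcs)
    })
    stage("greml-gwas", function() {
      keys <- unique(phenos[, c("variable", "statistic", "point")])
      her <- NULL
      for (i in seq_len(nrow(keys))) {
        d <- phenos[phenos$variable == keys$variable[i] &
                      phenos$statistic == keys$statistic[i] &
                      phenos$point == keys$point[i], ]
        y <- setNames(d$slope, d$chicken_id)
        fit <- greml(y, gen$grm, covariates = gen$pcs)
        her <- rbind(her, data.frame(
          variable = keys$variable[i], statistic = keys$statistic[i],
          point = keys$point[i], Vg = fit$Vg, se_Vg = fit$se_Vg,
          Ve = fit$Ve, se_Ve = fit$se_Ve, h2 = fit$h2, se_h2 = fit$se_h2,
          lrt_p = fit$lrt_p))
        if (isTRUE(cfg$gwas$run) && fit$lrt_p < cfg$gwas$alpha) {
          gw <- lmm_gwas(y, gen$g, covariates = gen$pcs, grm = gen$grm,
                         null = fit, mode = cfg$gwas$mode)
          thr <- bonferroni_thresholds(nrow(gw), cfg$gwas$alpha)
          gw$suggestive <- gw$p_value < thr$suggestive
          gw$genomewide <- gw$p_value < thr$genomewide
          f <- file.path(cfg$out_dir,
                         sprintf("gwas_%s_%s_P%s.tsv", keys$variable[i],
                                 keys$statistic[i], format(keys$point[i])))
          write.table(gw, f, sep = "\t", quote = FALSE, row.names = FALSE)
          if (!is.null(cfg$inputs$annotation) && any(gw$suggestive)) {
            ann <- annotate_hits(gw[gw$suggestive, ],
                                 read_gene_annotation(cfg$inputs$annotation),
                                 window = cfg$gwas$annotation_window)
            write.table(ann, sub("gwas_", "genes_", f), sep = "\t",
                        quote = FALSE, row.names = FALSE)
          }
        }
      }
      write.table(her, file.path(cfg$out_dir, "heritability.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      NULL
    })
  }

  outputs <- sort(list.files(cfg$out_dir, full.names = FALSE))
  outputs <- setdiff(outputs, "manifest.yaml")
  manifest$outputs <- lapply(setNames(outputs, outputs), function(f) {
    path <- file.path(cfg$out_dir, f)
    list(md5 = unname(tools::md5sum(path)),
         bytes = unname(file.size(path)))
  })
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(manifest)
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL        # run location is not part of the run identity
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[sort(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}
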
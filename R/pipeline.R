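#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `inputs` (paths to on-disk tables) or `simulation`
#' (arguments for [simulation_config()]) must be supplied.
#'
#' @param inputs list with paths: `betas`, `manifest`, optional `annotation`,
#'   `covariates`, `mqtl_flags`, `covariation`.
#' @param simulation list of [simulation_config()] arguments.
#' @param thresholds list; defaults: `variable = 0.05`,
#'   `intermediate = c(0.20, 0.80)`, `a_high = 0.8`, `covariation = 0.5`,
#'   `dmp = 1e-7`.
#' @param ewas list; optional: `exposure` (column name), `adjust` (character
#'   vector of adjustment covariates).
#' @param out_dir output directory.
#' @param seed master seed for every stochastic stage.
#' @return list with class `PipelineConfig`.
#' @export
pipeline_config <- function(inputs = NULL, simulation = NULL,
                            thresholds = list(), ewas = list(),
                            out_dir = "twinmeth_out", seed = 1L) {
  if (is.null(inputs) == is.null(simulation))
    stopf("provide exactly one of 'inputs' or 'simulation'")
  th <- modifyList(list(variable = 0.05, intermediate = c(0.20, 0.80),
    a_high = 0.8, covariation = 0.5, dmp = 1e-7), thresholds)
  stopifnot(th$variable > 0, th$variable < 1,
    th$intermediate[1] > 0, th$intermediate[2] < 1, th$dmp > 0, th$dmp < 1)
  structure(list(inputs = inputs, simulation = simulation, thresholds = th,
    ewas = ewas, out_dir = out_dir, seed = as.integer(seed)),
    class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file mirroring the [pipeline_config()] arguments.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$thresholds$intermediate))
    cfg$thresholds$intermediate <- as.numeric(cfg$thresholds$intermediate)
  pipeline_config(inputs = cfg$inputs, simulation = cfg$simulation,
    thresholds = cfg$thresholds %||% list(), ewas = cfg$ewas %||% list(),
    out_dir = cfg$out_dir %||% "twinmeth_out", seed = cfg$seed %||% 1L)
}

pipeline_data <- function(config) {
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% config$seed
    sim <- simulate_twin_cohort(do.call(simulation_config, sim_args))
    return(sim)
  }
  inp <- config$inputs
  betas <- read_beta_matrix(inp$betas)
  manifest <- read_pair_manifest(inp$manifest, betas = betas)
  annotation <- if (!is.null(inp$annotation)) read_probe_annotation(inp$annotation)
  covariates <- if (!is.null(inp$covariates))
    sample_covariates(data.table::fread(inp$covariates, data.table = FALSE))
  list(betas = betas, manifest = manifest, annotation = annotation,
    covariates = covariates, truth = NULL)
}

#' Run the full twin-methylation analysis pipeline
#'
#' Executes, in order: (optional) simulation, probe classification, twin
#' correlations and sign tests, genome-wide ACE decomposition, stratified
#' comparisons and level profiles, mQTL / covariation enrichment when scores
#' are available, and (optional) a cluster-robust exposure EWAS with the DMP
#' heritability report. Every table is written as TSV under `out_dir`
#' (`tables/`, `profiles/`, `logs/`, `config-echo.yaml`); excluded-probe and
#' pair counts are logged. Any stage error propagates with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (default all).
#' @return the output directory, invisibly.
#' @export
run_full_pipeline <- function(config,
                              stages = c("classify", "correlate", "ace",
                                "strata", "enrich", "ewas")) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  for (d in file.path(out, c("tables", "profiles", "logs")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "logs", "run.log")
  cat("", file = logf)
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  th <- config$thresholds

  dat <- run_stage("data", pipeline_data(config))
  log_line("data: %d probes x %d samples, %d MZ / %d DZ pairs",
    nrow(dat$betas), ncol(dat$betas), sum(dat$manifest$zygosity == "MZ"),
    sum(dat$manifest$zygosity == "DZ"))
  if (!is.null(config$simulation)) {
    write_beta_matrix(dat$betas, file.path(out, "tables", "betas.tsv"))
    write_pair_manifest(dat$manifest, file.path(out, "tables", "manifest.tsv"))
    data.table::fwrite(dat$truth$sites, file.path(out, "tables", "simulation_truth.tsv"),
      sep = "\t")
  }

  pc <- NULL
  if ("classify" %in% stages) {
    pc <- run_stage("classify", classify_probes(dat$betas,
      variable_threshold = th$variable,
      intermediate_low = th$intermediate[1],
      intermediate_high = th$intermediate[2]))
    data.table::fwrite(pc, file.path(out, "tables", "probe_classes.tsv"), sep = "\t")
    log_line("classify: %d variable, %d intermediate of %d probes",
      sum(pc$is_variable), sum(pc$is_intermediate), nrow(pc))
  }

  tc <- NULL
  if ("correlate" %in% stages) {
    tc <- run_stage("correlate", twin_correlations(dat$betas, dat$manifest))
    data.table::fwrite(tc, file.path(out, "tables", "twin_correlations.tsv"), sep = "\t")
    sign_rows <- list()
    sets <- list(all = tc$probe_id)
    if (!is.null(pc)) {
      sets$variable <- pc$probe_id[pc$is_variable]
      sets$intermediate <- pc$probe_id[pc$is_intermediate]
    }
    for (nm in names(sets)) {
      sub <- tc[tc$probe_id %in% sets[[nm]] & !is.na(tc$r_MZ) & !is.na(tc$r_DZ), ]
      if (!nrow(sub)) next
      st <- exact_sign_test(sum(sub$r_MZ > sub$r_DZ), nrow(sub))
      sign_rows[[nm]] <- data.frame(subset = nm, k = st$k_success,
        m = st$m_trials, p = st$p_two_sided, log10_p = st$log10_p,
        p_printed = st$p_printed)
      log_line("sign test [%s]: %g of %g sites more MZ-similar, p = %s",
        nm, st$k_success, st$m_trials, st$p_printed)
    }
    data.table::fwrite(do.call(rbind, sign_rows),
      file.path(out, "tables", "sign_tests.tsv"), sep = "\t")
    pp <- run_stage("correlate",
      pair_profile_correlation(dat$betas, dat$manifest, seed = config$seed))
    data.table::fwrite(pp, file.path(out, "tables", "pair_profile.tsv"), sep = "\t")
  }

  decomp <- NULL
  if ("ace" %in% stages) {
    decomp <- run_stage("ace",
      run_ace_genomewide(dat$betas, dat$manifest, dat$annotation))
    write_results_table(decomp, file.path(out, "tables", "ace_decomposition.tsv"))
    log_line("ace: %d fits, %d converged, %d chrY probes skipped",
      nrow(decomp), sum(decomp$converged, na.rm = TRUE),
      attr(decomp, "n_skipped_chrY") %||% 0L)
  }

  if ("strata" %in% stages && !is.null(decomp) && !is.null(pc)) {
    run_stage("strata", {
      dall <- decomp[decomp$stratum == "all", ]
      cmps <- list()
      for (nm in c("is_variable", "is_intermediate")) {
        memb <- pc[[nm]][match(dall$probe_id, pc$probe_id)]
        if (any(memb) && any(!memb))
          cmps[[nm]] <- cbind(stratification = sub("^is_", "", nm),
            compare_strata(dall, memb, labels = c(sub("^is_", "", nm), "other")))
      }
      if (length(cmps))
        data.table::fwrite(do.call(rbind, cmps),
          file.path(out, "tables", "strata_comparisons.tsv"), sep = "\t")
      mu <- pc$mean[match(dall$probe_id, pc$probe_id)]
      lp <- level_profile(mu, dall$A, min_n = max(5, min(50, nrow(dall) %/% 20)))
      data.table::fwrite(lp, file.path(out, "profiles", "A_by_level.tsv"), sep = "\t")
      if (!is.null(dat$annotation) && "tss_distance" %in% names(dat$annotation)) {
        prof <- positional_profile(dall, dat$annotation, min_n = 5)
        data.table::fwrite(prof, file.path(out, "profiles", "tss_profile.tsv"), sep = "\t")
      }
    })
  }

  if ("enrich" %in% stages && !is.null(decomp)) {
    run_stage("enrich", {
      dall <- decomp[decomp$stratum == "all", ]
      flags <- NULL
      if (!is.null(dat$truth)) {
        flags <- setNames(dat$truth$sites$is_mqtl, dat$truth$sites$probe_id)
      } else if (!is.null(config$inputs$mqtl_flags)) {
        ft <- data.table::fread(config$inputs$mqtl_flags, data.table = FALSE)
        flags <- setNames(as.logical(ft[[2]]), ft[[1]])
      }
      if (!is.null(flags) && any(flags)) {
        er <- mqtl_enrichment(dall, flags, a_threshold = th$a_high)
        data.table::fwrite(data.frame(
          prop_high = er$prop_high, prop_low = er$prop_low,
          odds_ratio = er$odds_ratio, p = er$p, log10_p = er$log10_p,
          n_excluded = er$n_unflagged_excluded),
          file.path(out, "tables", "mqtl_enrichment.tsv"), sep = "\t")
        log_line("enrich: mQTL flagged %.1f%% of high-A vs %.1f%% of low-A sites",
          100 * er$prop_high, 100 * er$prop_low)
      } else log_line("enrich: skipped (no usable mQTL flags or no high-A sites)")
      cov_scores <- NULL
      if (!is.null(config$inputs$covariation)) {
        ct <- data.table::fread(config$inputs$covariation, data.table = FALSE)
        cov_scores <- setNames(as.numeric(ct[[2]]), ct[[1]])
      }
      if (!is.null(cov_scores)) {
        cs <- covariation_stratified_heritability(dall, cov_scores,
          cutoff = th$covariation)
        data.table::fwrite(as.data.frame(cs[c("median_A_above", "median_A_below",
          "n_above", "n_below", "p", "pearson_r")]),
          file.path(out, "tables", "covariation_heritability.tsv"), sep = "\t")
      }
    })
  }

  if ("ewas" %in% stages) {
    covs <- dat$covariates
    exposure <- config$ewas$exposure %||% "smoking_status"
    if (!is.null(covs) && exposure %in% names(covs) &&
        length(unique(stats::na.omit(covs[[exposure]]))) > 1) {
      run_stage("ewas", {
        ew <- run_ewas(dat$betas, covs, exposure = exposure,
          adjust = config$ewas$adjust %||% character(),
          dmp_threshold = th$dmp)
        data.table::fwrite(ew, file.path(out, "tables", "ewas.tsv"), sep = "\t")
        log_line("ewas: %d sites tested, %d DMPs at p < %g",
          nrow(ew), sum(ew$is_dmp), th$dmp)
        dmps <- ew$probe_id[ew$is_dmp]
        if (length(dmps) && !is.null(decomp)) {
          rep_ <- dmp_heritability_report(dmps, decomp[decomp$stratum == "all", ],
            dat$betas, dat$manifest, covs, exposure = exposure)
          data.table::fwrite(rep_$strata_comparison,
            file.path(out, "tables", "dmp_strata.tsv"), sep = "\t")
          if (!is.null(rep_$sign_test))
            log_line("dmp report: r_MZ > r_DZ at %g of %g DMPs (concordant-unexposed), p = %s",
              rep_$sign_test$k_success, rep_$sign_test$m_trials,
              rep_$sign_test$p_printed)
        }
      })
    } else log_line("ewas: skipped (no usable exposure column)")
  }

  cfg_echo <- config
  class(cfg_echo) <- NULL
  yaml::write_yaml(cfg_echo, file.path(out, "config-echo.yaml"))
  invisible(out)
}
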
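#' @title End-to-end analysis pipeline
#' @description
#' Orchestrates the analysis stages (ingest or simulate, impute, regression,
#' intraclass correlations and model selection, univariate twin fits,
#' moderation fit, variance profile) from a single configuration, writing a
#' report bundle of JSON/CSV files. All randomness flows from one root seed
#' via fixed per-stage offsets, so a rerun with an identical configuration
#' reproduces every numeric output bit-exactly.
#' @name cli_report
NULL

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  config
}

write_stage_json <- function(x, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".json"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  path
}

#' Run the configured analysis pipeline
#'
#' @param config a list, or path to a YAML/JSON file, with elements:
#'   * `seed`: integer root seed (required whenever data are simulated);
#'   * `out_dir`: output directory for the report bundle;
#'   * `input`: either `list(csv = path, column_map = ...)` or
#'     `list(simulate = list(kind, spec))` with `kind` one of
#'     `"univariate"`, `"regression"`, `"moderation"` and `spec` a list of
#'     arguments for the matching `*_sim_spec()` constructor;
#'   * `stages`: character vector drawn from `"impute"`, `"regress"`,
#'     `"icc"`, `"univariate"`, `"moderation"`, `"profile"`;
#'   * optional per-stage settings: `regress$adjust`
#'     (`"minimal"`/`"full"`/both), `regress$mz_pairwise` (logical),
#'     `univariate$phenotype`, `univariate$model` (`"auto"` or a model
#'     label), `moderation$variant` (`"auto"`, `"full"`, `"no_shared_C"`),
#'     `profile$points` (grid size over the observed moderator range).
#' @return Invisibly, a list with the per-stage results and the paths of the
#'   files written. Any stage error aborts with the stage name; outputs of
#'   completed stages are preserved.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out_dir %||% stop("config needs 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages %||% character()
  simulating <- !is.null(cfg$input$simulate)
  if (simulating && is.null(cfg$seed)) {
    stop("config needs 'seed' when simulation is requested")
  }
  seed <- as.integer(cfg$seed %||% 0L) %% 1000000L
  results <- list()
  paths <- character()
  log <- list(
    package_version = as.character(utils::packageVersion("twingem")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, stages = stages, filters = list()
  )
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      write_stage_json(log, out_dir, "run_log")
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # ingest / simulate (per-stage seed offsets keep substreams independent)
  cohort <- run_stage("input", {
    if (simulating) {
      sim <- cfg$input$simulate
      spec_args <- sim$spec %||% list()
      spec_args$seed <- seed * 1000L + 1L
      switch(sim$kind %||% stop("input$simulate needs 'kind'"),
             univariate = simulate_univariate(
               do.call(univariate_sim_spec, spec_args)),
             regression = simulate_regression_cohort(
               do.call(regression_sim_spec, spec_args)),
             moderation = simulate_moderation(
               do.call(moderation_sim_spec, spec_args)),
             stop("unknown simulate kind: ", sim$kind))
    } else if (!is.null(cfg$input$csv)) {
      if (!file.exists(cfg$input$csv)) {
        stop("input file not found: ", cfg$input$csv)
      }
      read_cohort(cfg$input$csv, column_map = cfg$input$column_map)
    } else {
      stop("config needs input$csv or input$simulate")
    }
  })
  log$counts <- cohort$meta
  paths <- c(paths, write_stage_json(cohort$meta, out_dir, "cohort_meta"))

  if ("impute" %in% stages) {
    cohort <- run_stage("impute", suppressMessages(
      impute_covariates_median(cohort)))
    log$filters$imputed <- as.list(attr(cohort, "imputation_counts"))
  }

  if ("regress" %in% stages) {
    results$regress <- run_stage("regress", {
      adj <- cfg$regress$adjust %||% c("minimal", "full")
      out <- list()
      for (a in adj) {
        f <- fit_individual(cohort, a)
        out[[paste0("individual_", a)]] <- list(
          coefficients = as.list(f$coefficients),
          robust_se = as.list(f$robust_se), r2 = f$r2,
          n_used = f$n_used, clusters = f$cluster_count)
      }
      if (isTRUE(cfg$regress$mz_pairwise %||% TRUE)) {
        for (a in adj) {
          f <- fit_mz_pairwise(cohort, a)
          out[[paste0("mz_pairwise_", a)]] <- list(
            coefficients = as.list(f$coefficients),
            se = as.list(f$robust_se), r2 = f$r2, n_pairs = f$n_used)
        }
      }
      out
    })
    paths <- c(paths, write_stage_json(results$regress, out_dir, "regress"))
  }

  uni_phen <- cfg$univariate$phenotype %||% "walkability"
  resid_col <- paste0(uni_phen, "_resid")

  if (any(c("icc", "univariate", "moderation", "profile") %in% stages)) {
    cohort <- run_stage("residualize", {
      ch <- residualize_phenotype(cohort, uni_phen)
      other <- setdiff(c("walkability", "bmi"), uni_phen)
      if (any(c("moderation", "profile") %in% stages) &&
          any(!is.na(cohort$individuals[[other]]))) {
        ch <- residualize_phenotype(ch, other)
      }
      ch
    })
  }

  if ("icc" %in% stages) {
    results$icc <- run_stage("icc", {
      icc_mz <- intraclass_correlation(cohort, "MZ", resid_col)
      icc_dz <- intraclass_correlation(cohort, "DZ", resid_col)
      list(
        MZ = list(icc = icc_mz$icc, ci95 = icc_mz$ci95,
                  n_pairs = icc_mz$n_pairs),
        DZ = list(icc = icc_dz$icc, ci95 = icc_dz$ci95,
                  n_pairs = icc_dz$n_pairs),
        falconer = falconer_decomposition(icc_mz$icc, icc_dz$icc),
        base_model = select_base_model(icc_mz$icc, icc_dz$icc)
      )
    })
    paths <- c(paths, write_stage_json(results$icc, out_dir, "icc"))
  }

  if ("univariate" %in% stages) {
    results$univariate <- run_stage("univariate", {
      choice <- cfg$univariate$model %||% "auto"
      base <- if (choice == "auto") {
        icc_mz <- intraclass_correlation(cohort, "MZ", resid_col)
        icc_dz <- intraclass_correlation(cohort, "DZ", resid_col)
        select_base_model(icc_mz$icc, icc_dz$icc)
      } else {
        choice
      }
      nested <- if (base == "ACE") c("ACE", "AE", "CE", "E") else
        c("ADE", "AE", "E")
      fits <- lapply(nested, function(m) {
        fit_univariate(cohort, m, resid_col, ci = "profile")
      })
      cmp <- compare_models(fits, reference = base)
      tab <- do.call(rbind, lapply(fits, function(f) {
        s <- f$standardized
        data.frame(model = f$model,
                   component = s$component, proportion = s$proportion,
                   ci_lower = s$ci_lower, ci_upper = s$ci_upper,
                   aic = f$aic)
      }))
      utils::write.csv(tab, file.path(out_dir, "univariate_components.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(cmp),
                       file.path(out_dir, "univariate_comparison.csv"),
                       row.names = FALSE)
      list(base_model = base, fits = fits, comparison = cmp)
    })
    paths <- c(paths, file.path(out_dir, c("univariate_components.csv",
                                           "univariate_comparison.csv")))
  }

  mod_fit <- NULL
  if ("moderation" %in% stages) {
    mod_out <- run_stage("moderation", {
      variant <- cfg$moderation$variant %||% "auto"
      if (variant == "auto") {
        cmpv <- compare_moderation_variants(cohort)
        fit <- if (cmpv$prefer_no_shared_C) cmpv$fit_no_shared_C else
          cmpv$fit_full
        list(fit = fit,
             summary = list(selected = fit$variant,
                            aic_diff = cmpv$aic_diff, lrt = cmpv$lrt,
                            params = as.list(fit$params),
                            loglik = fit$loglik, aic = fit$aic))
      } else {
        fit <- fit_moderation(cohort, variant)
        list(fit = fit,
             summary = list(selected = variant,
                            params = as.list(fit$params),
                            loglik = fit$loglik, aic = fit$aic))
      }
    })
    mod_fit <- mod_out$fit
    results$moderation <- mod_out$summary
    paths <- c(paths, write_stage_json(results$moderation, out_dir,
                                       "moderation"))
  }

  if ("profile" %in% stages) {
    results$profile <- run_stage("profile", {
      if (is.null(mod_fit)) stop("profile stage requires moderation stage")
      m_obs <- cohort$individuals[[mod_fit$moderator]]
      npts <- cfg$profile$points %||% 101L
      grid <- seq(min(m_obs, na.rm = TRUE), max(m_obs, na.rm = TRUE),
                  length.out = npts)
      vp <- variance_profile(mod_fit, grid)
      utils::write.csv(vp$profile,
                       file.path(out_dir, "variance_profile.csv"),
                       row.names = FALSE)
      vp
    })
    paths <- c(paths, file.path(out_dir, "variance_profile.csv"))
  }

  paths <- c(paths, write_stage_json(log, out_dir, "run_log"))
  invisible(list(cohort = cohort, results = results, paths = paths,
                 log = log))
}
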
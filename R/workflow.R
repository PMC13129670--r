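#' Run the full MRD workflow from a YAML configuration
#'
#' Orchestrates the four phases — pre-processing, model fitting (or
#' selection), classification of new data, and survival/landmark
#' post-processing — and writes a static report bundle: the fitted model
#' as versioned JSON, membership/entropy/discriminant tables and survival
#' summaries as CSV/JSON, plus a run manifest (config echo, seed, input
#' digests, package version, per-phase timings). All randomness is
#' governed by the single `seed` field.
#'
#' Configuration fields: `seed`; `output_dir`; either `simulate`
#' (`n_subjects`, `tissue`, optional generator overrides) or
#' `measurements` (+ optional `clinical`) CSV paths; `tissue`;
#' `min_timepoints`; `fit` (`G`, `p`, optional `h`, `n_starts`);
#' optional `classify` (`measurements` path, `cutoff`, `entropy_max`);
#' optional `survival: true`; optional `landmark`
#' (`landmarks`, `min_timepoints`).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return invisibly, a list with the fit, tables and output paths.
#' @export
run_workflow <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- cfg$output_dir %||% "mrdflow-report"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  timings <- list()
  tick <- function(phase, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop_mrdflow("workflow phase '", phase, "' failed: ",
                   conditionMessage(e), class = "mrdflow_phase_error"))
    timings[[phase]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  digests <- list()
  ## phase 1: pre-processing (load or simulate)
  prep <- tick("preprocess", {
    if (!is.null(cfg$simulate)) {
      sc <- cfg$simulate
      conf <- simulation_config(
        n_subjects = sc$n_subjects %||% 120,
        baseline_hazard = sc$baseline_hazard %||% 0.006,
        study_end = sc$study_end %||% 72, seed = seed)
      sim <- simulate_mrd_study(config = conf, tissue = sc$tissue %||% "BM")
      mpath <- file.path(out_dir, "simulated_measurements.csv")
      cpath <- file.path(out_dir, "simulated_clinical.csv")
      write_cohort(sim$cohort, mpath, cpath)
      utils::write.csv(sim$truth, file.path(out_dir, "simulated_truth.csv"),
                       row.names = FALSE)
      sim$cohort
    } else {
      if (is.null(cfg$measurements))
        stop("config must provide either 'simulate' or 'measurements'")
      digests$measurements <- unname(tools::md5sum(cfg$measurements))
      if (!is.null(cfg$clinical))
        digests$clinical <- unname(tools::md5sum(cfg$clinical))
      read_cohort(cfg$measurements, cfg$clinical, tissue = cfg$tissue)
    }
  })
  min_tp <- cfg$min_timepoints %||% 3
  cohort <- filter_cohort(prep, min_tp)

  ## phase 2: predictive model definition
  fit <- tick("fit", {
    fc <- cfg$fit %||% list()
    fit_fcm(cohort, G = fc$G %||% 4, p = fc$p %||% 5,
            h = fc$h %||% max((fc$G %||% 4) - 1, 1),
            n_starts = fc$n_starts %||% 10, seed = seed)
  })
  model_path <- file.path(out_dir, "model.json")
  write_fcm_model(fit$model, model_path,
                  extra = list(seed = seed, min_timepoints = min_tp))
  memb <- data.frame(patient_id = fit$patient_id, fit$memberships,
                     assignment = fit$assignments, check.names = FALSE)
  utils::write.csv(memb, file.path(out_dir, "memberships.csv"),
                   row.names = FALSE)
  grid <- seq(fit$model$basis$range[1], fit$model$basis$range[2],
              length.out = 100)
  D <- discriminant_functions(fit$model, grid)
  utils::write.csv(data.frame(time = grid, D, check.names = FALSE),
                   file.path(out_dir, "discriminant_functions.csv"),
                   row.names = FALSE)

  ## phase 3: model abstraction (training-cohort entropy; optional new data)
  cls <- tick("classify", {
    res <- classify_cohort(fit$model, cohort)
    ent <- entropy_vs_length_table(res)
    utils::write.csv(ent$table, file.path(out_dir, "entropy.csv"),
                     row.names = FALSE)
    new_tab <- NULL
    if (!is.null(cfg$classify)) {
      cc <- cfg$classify
      newco <- read_cohort(cc$measurements, tissue = cfg$tissue)
      newco <- filter_cohort(newco, cc$min_timepoints %||% min_tp)
      newres <- classify_cohort(fit$model, newco,
                                cutoff = cc$cutoff %||% 0.6,
                                entropy_max = cc$entropy_max %||% 1.0)
      new_tab <- classification_table(newres)
      utils::write.csv(new_tab, file.path(out_dir, "classification.csv"),
                       row.names = FALSE)
    }
    list(train = res, entropy = ent, new = new_tab)
  })

  ## phase 4: post-processing survival / landmark
  surv <- NULL
  if (isTRUE(cfg$survival) || !is.null(cfg$landmark)) {
    if (is.null(cohort$clinical))
      stop_mrdflow("survival analysis requested but the config has no ",
                   "'clinical' table", class = "mrdflow_config_error")
    surv <- tick("survival", {
      groups <- stats::setNames(merge_groups(fit$assignments),
                                fit$patient_id)
      rec <- survival_records(cohort$clinical, groups)
      km <- lapply(split(rec, rec$group), km_estimate)
      med <- data.frame(
        group = names(km),
        n = as.numeric(table(rec$group)[names(km)]),
        median_ttp = vapply(km, function(k)
          if (k$median_reached) k$median else NA_real_, 0))
      utils::write.csv(med, file.path(out_dir, "median_ttp.csv"),
                       row.names = FALSE)
      lr <- logrank_test(rec)
      hr <- cox_hr(rec, reference = "FAVORABLE")
      jsonlite::write_json(list(logrank = lr, cox = hr),
                           file.path(out_dir, "survival.json"),
                           digits = NA, auto_unbox = TRUE)
      lm <- NULL
      if (!is.null(cfg$landmark)) {
        lc <- cfg$landmark
        lm <- landmark_analysis(fit$model, cohort,
                                landmarks = unlist(lc$landmarks),
                                min_timepoints = lc$min_timepoints %||% min_tp)
        lm_tab <- data.frame(
          landmark = vapply(lm, `[[`, 0, "landmark"),
          n_at_risk = vapply(lm, `[[`, 0L, "n_at_risk"),
          n_classified = vapply(lm, `[[`, 0L, "n_classified"),
          evaluable = vapply(lm, `[[`, TRUE, "evaluable"),
          logrank_p = vapply(lm, function(x)
            if (x$evaluable) x$logrank$p_value else NA_real_, 0))
        utils::write.csv(lm_tab, file.path(out_dir, "landmark.csv"),
                         row.names = FALSE)
      }
      list(records = rec, km = km, logrank = lr, cox = hr, landmark = lm)
    })
  }

  manifest <- list(
    format = "mrdflow-manifest", version = "1.0",
    package_version = as.character(utils::packageVersion("mrdflow")),
    seed = seed, config = cfg, input_digests = digests,
    timings_sec = as.list(timings))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(list(cohort = cohort, fit = fit, classification = cls,
                 survival = surv, output_dir = out_dir))
}
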
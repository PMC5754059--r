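#' Run the full projection pipeline
#'
#' End-to-end orchestration: generate the synthetic base population and
#' true parameters, simulate an estimation panel and refit the transition
#' models (estimation round trip), calibrate the mortality- and
#' incidence-based scenarios, project all scenarios to the horizon, value
#' the differences, and write every artifact with a checksum manifest.
#' Two runs with the same config and master seed produce identical
#' manifests.
#'
#' @param config settings from [default_config()] (schema-checked).
#' @param out_dir output directory (created if missing).
#' @param master_seed master seed; all stage seeds derive from it.
#' @param refit use panel-refitted transition models for projection
#'   (default FALSE: project with the generating parameters).
#' @return (invisibly) a list with the key in-memory artifacts: population,
#'   truth, calibrations, projections, valuation tables, manifest path.
#' @export
run_pipeline <- function(config, out_dir, master_seed = 1L, refit = FALSE) {
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed (master_seed=", master_seed,
           "): ", conditionMessage(e), call. = FALSE))
    message(sprintf("[pipeline] %-10s %6.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  pop <- stage("generate", {
    p <- make_base_population(config$n, seed = substream(master_seed, 1L),
                              config = config)
    write_population(p, file.path(out_dir, "population.csv"),
                     seed = master_seed, config = config)
    p
  })
  truth <- stage("truth", {
    tr <- make_true_parameters(seed = substream(master_seed, 2L), config)
    write_model_set(tr$transitions, file.path(out_dir, "transition_models.json"))
    tr
  })
  fitres <- stage("fit", {
    panel <- simulate_panel(pop, truth, n_cycles = 4L,
                            seed = substream(master_seed, 3L))
    fit_transition_models(panel, truth$transitions, skip_failures = TRUE)
  })
  truth_run <- truth
  if (refit) truth_run$transitions <- fitres$models

  seeds <- seq_len(max(2L, length(config$calibration_seeds))) + master_seed
  cal <- stage("calibrate", {
    res <- list(
      mortality = calibrate_multiplier(
        scenario_spec("mortality",
                      target_reduction = config$scenario$target_reduction),
        pop, truth_run, seeds = seeds, tol = config$scenario$tol),
      incidence = calibrate_multiplier(
        scenario_spec("incidence",
                      target_reduction = config$scenario$target_reduction),
        pop, truth_run, seeds = seeds, tol = config$scenario$tol))
    jsonlite::write_json(
      lapply(res, function(r) r[c("multiplier", "achieved_reduction",
                                  "baseline_reduction",
                                  "additional_reduction", "converged",
                                  "infeasible", "iterations")]),
      file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
    res
  })
  specs <- list(
    baseline = scenario_spec("baseline"),
    mortality = scenario_spec("mortality",
                              multiplier = cal$mortality$multiplier),
    incidence = scenario_spec("incidence",
                              multiplier = cal$incidence$multiplier))
  projections <- stage("project", {
    runs <- lapply(specs, function(sp)
      run_projection(pop, truth_run, sp, horizon = config$horizon,
                     seed = substream(master_seed, 7L)))
    metrics <- do.call(rbind, lapply(runs, projection_metrics))
    utils::write.csv(metrics, file.path(out_dir, "projection_metrics.csv"),
                     row.names = FALSE)
    idx <- cost_index_table(runs)
    utils::write.csv(idx, file.path(out_dir, "cost_indices.csv"),
                     row.names = FALSE)
    runs
  })
  valuation <- stage("value", {
    reps <- config$replication
    tables <- lapply(specs[c("mortality", "incidence")], function(sp) {
      rs <- run_replications(pop, truth_run, sp,
                             n_param_draws = reps$n_param_draws,
                             n_sim_seeds = reps$n_sim_seeds,
                             master_seed = substream(master_seed, 11L),
                             horizon = config$horizon)
      build_valuation_table(rs, rate = config$valuation$discount_rate,
                            vsly = config$valuation$vsly,
                            horizons = config$valuation$horizons)
    })
    out <- do.call(rbind, lapply(names(tables), function(nm) {
      tt <- tables[[nm]]$table
      tt$scenario <- nm
      tt
    }))
    utils::write.csv(out, file.path(out_dir, "valuation.csv"),
                     row.names = FALSE)
    tables
  })
  stage("report", {
    write_config(config, file.path(out_dir, "config.yaml"))
    meta <- list(master_seed = master_seed, config_hash = config_hash(config),
                 package_version = as.character(utils::packageVersion("cvdmicrosim")))
    jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- setdiff(list.files(out_dir), "manifest.json")
    manifest <- data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA)
    NULL
  })
  invisible(list(population = pop, truth = truth_run, fits = fitres,
                 calibration = cal, projections = projections,
                 valuation = valuation,
                 manifest = file.path(out_dir, "manifest.json")))
}

#' Cross-scenario cost index table
#'
#' Normalizes every scenario's per-category annual cost series to 100 at
#' the *baseline* scenario's 2012 value, so indices are comparable across
#' scenarios.
#'
#' @param runs named list of `cvd_projection` objects including
#'   `"baseline"`.
#' @return data frame `(year, category, scenario, dollars, index)`.
#' @export
cost_index_table <- function(runs) {
  if (!"baseline" %in% names(runs))
    stop("cost_index_table: needs a 'baseline' run")
  k12 <- match(2012L, runs$baseline$years)
  out <- list()
  for (nm in names(runs)) {
    run <- runs[[nm]]
    ok <- run$years >= 2012L
    for (cat in COST_CATEGORIES) {
      base_value <- runs$baseline$costs[cat, k12]
      out[[length(out) + 1L]] <- data.frame(
        year = run$years[ok], category = cat, scenario = nm,
        dollars = as.numeric(run$costs[cat, ok]),
        index = as.numeric(normalize_index(run$costs[cat, ok], 2012L,
                                           base_value)))
    }
  }
  do.call(rbind, out)
}
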
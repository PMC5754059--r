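#' Default generation and simulation settings
#'
#' Returns the package's stated synthetic world: the demographic structure,
#' age-specific disease prevalence, risk-factor rates, hazard parameters,
#' cost parameters, trend and growth schedules, and scenario/valuation
#' defaults used by every stage of the microsimulation.  All entries can be
#' overridden by editing the returned list; `validate_config()` is applied
#' by every consumer.
#'
#' Prevalence curves are stepwise by 10-year age band (30-39, 40-49, ...,
#' 100-110) and were chosen so that, weighted by the default age structure,
#' overall prevalence among adults 30+ lands near published Canadian levels
#' circa 2010-2012 (hypertension about 29\%, heart disease about 7\%).
#'
#' @param n number of simulated persons in the base population.
#' @param base_year first calendar year of the simulation (a cycle boundary).
#' @param horizon last projected calendar year.
#' @return a named list of settings with class `msim_config`.
#' @export
#' @examples
#' cfg <- default_config(n = 1000)
#' cfg$prevalence$hypertension
default_config <- function(n = 20000, base_year = 2010, horizon = 2050) {
  cfg <- list(
    schema_version = 1L,
    base_year = as.integer(base_year),
    horizon = as.integer(horizon),
    n = as.integer(n),
    # Total persons represented by the survey weights (adults 30+).
    represented_population = 5.0e6,
    demography = list(
      # 5-year band shares 30-34 .. 105-110, roughly an aged Western
      # population in 2010; normalized internally.
      age_band_weights = c(8.5, 8.5, 9.0, 9.5, 9.5, 9.0, 8.5, 7.0,
                           5.5, 4.5, 3.5, 2.2, 1.0, 0.30, 0.05, 0.01),
      male = 0.49,
      education = c(0.18, 0.35, 0.47),  # < secondary, secondary, post-sec.
      immigrant = 0.13
    ),
    # Stepwise prevalence by 10-year band: 30s, 40s, ..., 100s.
    prevalence = list(
      diabetes      = c(0.025, 0.050, 0.090, 0.140, 0.180, 0.200, 0.200, 0.200),
      hypertension  = c(0.090, 0.160, 0.290, 0.420, 0.500, 0.550, 0.570, 0.570),
      stroke        = c(0.004, 0.008, 0.015, 0.025, 0.045, 0.070, 0.090, 0.090),
      cancer        = c(0.010, 0.020, 0.040, 0.080, 0.130, 0.170, 0.190, 0.190),
      heart_disease = c(0.015, 0.030, 0.060, 0.100, 0.160, 0.220, 0.260, 0.280),
      lung_disease  = c(0.020, 0.030, 0.050, 0.080, 0.110, 0.130, 0.140, 0.140),
      dementia      = c(0.001, 0.002, 0.004, 0.012, 0.040, 0.110, 0.250, 0.350)
    ),
    # Shared logistic latent factor inducing hypertension/heart-disease
    # co-occurrence in the base population (loading on the latent).
    comorbidity_loading = 0.8,
    risk_factors = list(
      smoking = 0.20,
      obesity = 0.17,
      activity_limited = c(0.06, 0.08, 0.11, 0.16, 0.23, 0.33, 0.45, 0.60),
      cognitive_base = 0.01,
      in_ltc = c(0, 0, 0.001, 0.003, 0.010, 0.040, 0.120, 0.250)
    ),
    # Survey weights drawn uniformly in (1 - jitter, 1 + jitter) x equal.
    weight_jitter = 0.2,
    # Decade trends (as fractions per decade) applied to entry cohorts,
    # damped 1, 1/2, 1/4, 0 across the projected decades.
    trends = list(smoking = -0.04, obesity = 0.03, post_secondary = 0.04),
    # Exogenous annual all-cause mortality improvement (hazard-scale
    # multiplier (1 - delta)^(year - 2012)), standing in for alignment to
    # official projections.
    mortality_improvement = 0.021,
    # Stand-in low/high-growth demographic projections bracketing the 2050
    # population represented (30+).
    pop_2050_bounds = c(low = 4.8e6, high = 8.0e6),
    entry_cohort = list(schedule = "constant_base"),
    growth_schedule = list(
      breaks = c(2012L, 2018L, 2028L, 2038L),
      rates = c(0.015, 0.010, 0.005, 0.0)
    ),
    costs = list(
      unit_costs = c(hospital_nights = 1100, specialist_visits = 78,
                     generalist_visits = 55),
      # Share of physician consultation cost incurred in a hospital
      # setting, folded into the hospitalization category.
      hospital_share = c(specialist_visits = 0.30, generalist_visits = 0.10)
    ),
    scenario = list(
      target_reduction = 0.25,
      target_window = c(2012L, 2024L),
      ramp_mortality = c(2012L, 2024L),
      ramp_incidence = c(2012L, 2022L),
      tol = 0.005
    ),
    valuation = list(
      discount_rate = 0.03,
      vsly = 200000,
      horizons = c(2020L, 2035L, 2050L)
    ),
    replication = list(n_param_draws = 2L, n_sim_seeds = 2L),
    calibration_seeds = 1:10
  )
  class(cfg) <- c("msim_config", "list")
  validate_config(cfg)
  cfg
}

#' Validate a configuration list
#'
#' Checks structural and numerical requirements (prevalence in \[0, 1\],
#' positive population sizes, coherent year windows, positive unit costs,
#' non-increasing non-negative growth rates).  Errors name the offending
#' field path.
#'
#' @param config a list as returned by [default_config()].
#' @return the config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  need <- c("base_year", "horizon", "n", "represented_population",
            "demography", "prevalence", "risk_factors", "growth_schedule",
            "costs", "scenario", "valuation", "trends")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop_config("missing fields: ", paste(miss, collapse = ", "))
  if (config$n < 1) stop_config("n: must be >= 1")
  if (config$horizon <= config$base_year)
    stop_config("horizon: must exceed base_year")
  if (config$represented_population <= 0)
    stop_config("represented_population: must be positive")
  aw <- config$demography$age_band_weights
  if (is.null(aw) || length(aw) != N_AGE_BANDS || any(aw < 0) || sum(aw) <= 0)
    stop_config("demography$age_band_weights: need ", N_AGE_BANDS,
                " non-negative weights with positive sum")
  for (d in names(config$prevalence)) {
    p <- config$prevalence[[d]]
    if (any(p < 0 | p > 1))
      stop_config("prevalence$", d, ": targets must lie in [0, 1]")
  }
  ed <- config$demography$education
  if (length(ed) != 3 || abs(sum(ed) - 1) > 1e-8)
    stop_config("demography$education: three shares summing to 1")
  gs <- config$growth_schedule
  if (any(gs$rates < 0) || is.unsorted(rev(gs$rates)))
    stop_config("growth_schedule$rates: must be non-negative and non-increasing")
  if (any(config$costs$unit_costs <= 0))
    stop_config("costs$unit_costs: must be positive")
  sc <- config$scenario
  if (sc$target_reduction <= 0 || sc$target_reduction >= 1)
    stop_config("scenario$target_reduction: must be in (0, 1)")
  invisible(config)
}

#' Read and write configuration files
#'
#' Configurations round-trip through YAML (the schema carries a
#' `schema_version` field) or JSON, chosen by file extension.
#'
#' @param config a configuration list.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_config()` returns a validated `msim_config` list.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  # restore integer-ish fields and names lost in serialization
  cfg$costs$unit_costs <- unlist(cfg$costs$unit_costs)
  cfg$costs$hospital_share <- unlist(cfg$costs$hospital_share)
  cfg$pop_2050_bounds <- unlist(cfg$pop_2050_bounds)
  class(cfg) <- c("msim_config", "list")
  validate_config(cfg)
  cfg
}

#' Hash a configuration
#'
#' MD5 of the canonical JSON serialization; recorded in output metadata so
#' artifacts can be traced to the exact settings that produced them.
#'
#' @param config a configuration list.
#' @return a character scalar (32 hex digits).
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
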
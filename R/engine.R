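#' Damped secular trend value
#'
#' Prolongs a past per-decade trend one decade into the projection, halves
#' it each subsequent decade, and sets it to zero from 2040 on (damping
#' factors exactly 1, 1/2, 1/4, 0 by decade).  Linear within decades.
#'
#' @param base baseline proportion at `base_year`.
#' @param delta_per_decade trend as a fraction per decade (signed).
#' @param year calendar year (scalar or vector).
#' @param base_year start of the first projected decade (default 2010).
#' @return the trend-adjusted proportion, clamped to \[0, 1\].
#' @export
#' @examples
#' trend_value(0.20, -0.04, c(2020, 2030, 2040, 2050))  # 0.16 0.14 0.13 0.13
trend_value <- function(base, delta_per_decade, year, base_year = 2010L) {
  t <- pmax(year - base_year, 0)
  exposure <- pmin(t, 10) + 0.5 * clamp(t - 10, 0, 10) +
    0.25 * clamp(t - 20, 0, 10)
  clamp(base + delta_per_decade * exposure / 10, 0, 1)
}

#' Add an entry cohort of 30- and 31-year-olds
#'
#' New persons enter the simulation each cycle at ages 30 and 31 with
#' weights from the cohort-size schedule.  Entrant smoking, obesity and
#' education reflect the damped secular trends evaluated at the entry year;
#' disease flags are drawn from the youngest prevalence band.
#'
#' @param state a `population_state` at a cycle boundary.
#' @param year entry year (must equal `state$year`).
#' @param config generation settings.
#' @param cohort_weight total represented weight of the entering cohort
#'   (persons); 0 leaves the state unchanged.
#' @param n_entrants number of simulated records carrying that weight.
#' @param seed integer seed.
#' @param next_id first person_id to assign.
#' @return the `population_state` with entrants appended.
#' @export
add_entry_cohort <- function(state, year, config, cohort_weight, n_entrants,
                             seed = 1L, next_id = NULL) {
  if (year != state$year)
    stop("add_entry_cohort: year ", year, " != state year ", state$year)
  if (is.null(cohort_weight))
    stop_config("missing cohort-size schedule")
  if (cohort_weight <= 0 || n_entrants < 1L) return(state)
  set.seed(seed)
  n <- as.integer(n_entrants)
  tr <- config$trends
  base_year <- config$base_year
  smoke_rate <- trend_value(config$risk_factors$smoking, tr$smoking, year,
                            base_year)
  obese_rate <- trend_value(config$risk_factors$obesity, tr$obesity, year,
                            base_year)
  ed <- config$demography$education
  ed3 <- trend_value(ed[3], tr$post_secondary, year, base_year)
  ed12 <- ed[1:2] * (1 - ed3) / (1 - ed[3])
  ed_prob <- c(ed12, ed3)

  age <- rep(c(30L, 31L), length.out = n)
  band10 <- decade_band(age)
  flags <- lapply(DISEASES, function(d)
    stats::runif(n) < config$prevalence[[d]][band10])
  names(flags) <- DISEASES
  entrants <- data.frame(
    person_id = (next_id %||% (max(state$persons$person_id) + 1L)) +
      seq_len(n) - 1L,
    age = age,
    sex = ifelse(stats::runif(n) < config$demography$male, "male", "female"),
    education = sample.int(3L, n, replace = TRUE, prob = ed_prob),
    immigrant = stats::runif(n) < config$demography$immigrant,
    flags,
    smoker = stats::runif(n) < smoke_rate,
    obese = stats::runif(n) < obese_rate,
    activity_limited = stats::runif(n) <
      config$risk_factors$activity_limited[band10],
    cognitively_impaired = stats::runif(n) < config$risk_factors$cognitive_base,
    in_ltc = FALSE,
    alive = TRUE,
    weight = cohort_weight / n,
    stringsAsFactors = FALSE)
  state$persons <- rbind(state$persons, entrants)
  state
}

#' Directly age-standardized rate
#'
#' Weighted average of age-band-specific rates under a fixed reference age
#' distribution.
#'
#' @param rates per-band rates (NA marks an empty band).
#' @param reference reference weights summing to 1.
#' @return the standardized rate.
#' @export
direct_standardized_rate <- function(rates, reference) {
  if (abs(sum(reference) - 1) > 1e-8)
    stop("direct_standardized_rate: reference weights must sum to 1")
  bad <- which(!is.finite(rates) & reference > 0)
  if (length(bad))
    stop("direct_standardized_rate: empty age band with nonzero reference ",
         "weight: ", paste(names(rates)[bad] %||% bad, collapse = ", "))
  sum(reference[reference > 0] * rates[reference > 0])
}

#' Run a full projection
#'
#' Orchestrates the four-stage microsimulation from the base population to
#' `horizon` in two-year cycles: joint transitions from the lagged state
#' (with the scenario's ramped multipliers and the exogenous mortality
#' improvement), exit at age 110, entry cohorts at ages 30-31 through 2050,
#' and per-year demographic, mortality and cost aggregates.  Deterministic
#' given `seed`; the demographic ledger is checked every cycle.
#'
#' @param base the base `population_state`.
#' @param truth a `synthetic_truth`.
#' @param scenario a [scenario_spec()]; default baseline.
#' @param horizon final calendar year (`>= base$year + 2`).
#' @param seed integer seed.
#' @param compute_costs compute per-year cost aggregates (default TRUE).
#' @return an object of class `cvd_projection`; see Details.
#' @details The returned object carries, per even reporting year: total live
#'   weight, live weight by 5-year age band, weight with cardiovascular
#'   disease, weighted deaths split by lagged CVD status and band,
#'   person-years lived, per-category costs (years >= 2012), entrants and
#'   age-110 exits, and the annualized person-years series used for
#'   life-year accounting.
#' @export
run_projection <- function(base, truth, scenario = scenario_spec("baseline"),
                           horizon = 2050L, seed = 1L, compute_costs = TRUE) {
  if (horizon < base$year + 2L)
    stop("run_projection: horizon before first cycle end")
  config <- truth$config
  persons <- base$persons[base$persons$alive, , drop = FALSE]
  # constant entry-cohort schedule: the base population's 30-31 weight
  is3031 <- persons$age %in% c(30L, 31L)
  cohort_weight <- sum(persons$weight[is3031])
  n_entrants <- max(2L, sum(is3031))
  next_id <- max(persons$person_id) + 1L

  years <- seq(base$year + 2L, horizon, by = 2L)
  K <- length(years)
  nb <- N_AGE_BANDS
  pop_total <- entrants_w <- deaths_w <- deaths_cvd_w <- ageouts_w <-
    person_years <- cvd_pop <- stats::setNames(numeric(K), years)
  live_start <- live_end <- stats::setNames(numeric(K), years)
  pop_by_band <- deaths_by_band <- deaths_cvd_by_band <-
    matrix(0, nb, K, dimnames = list(AGE_BAND_LABELS, years))
  cost_mat <- matrix(NA_real_, 3, K, dimnames = list(COST_CATEGORIES, years))
  base_band <- band_sum(persons$age, persons$weight)
  base_total <- sum(persons$weight)
  delta <- truth$mortality_improvement

  cost_at <- function(p, yr) {
    st <- structure(list(year = yr, persons = p, cycle_length = 2L),
                    class = "population_state")
    aggregate_costs(st, truth$costs, config$growth_schedule, yr,
                    config$costs$hospital_share)
  }

  for (k in seq_len(K)) {
    y_end <- years[k]
    mult <- scenario_multipliers(scenario, y_end)
    mult$death_all <- (1 - delta)^max(0, y_end - 2012L)
    step <- cycle_step(persons, truth$transitions, mult,
                       substream(seed, 2L * k))
    sm <- step$summary
    persons <- step$persons[step$persons$alive, , drop = FALSE]

    ent_w <- if (y_end <= 2050L) cohort_weight else 0
    if (ent_w > 0) {
      st <- structure(list(year = y_end, persons = persons, cycle_length = 2L),
                      class = "population_state")
      st <- add_entry_cohort(st, y_end, config, ent_w, n_entrants,
                             substream(seed, 2L * k + 1L), next_id)
      persons <- st$persons
      next_id <- next_id + n_entrants
    }

    live_start[k] <- sm$live_start
    deaths_w[k] <- sm$deaths
    deaths_cvd_w[k] <- sm$deaths_cvd
    ageouts_w[k] <- sm$ageouts
    entrants_w[k] <- ent_w
    person_years[k] <- sm$person_years
    live_end[k] <- sum(persons$weight)
    pop_total[k] <- live_end[k]
    pop_by_band[, k] <- band_sum(persons$age, persons$weight)
    deaths_by_band[, k] <- sm$deaths_by_band
    deaths_cvd_by_band[, k] <- sm$deaths_cvd_by_band
    cvd_pop[k] <- sum(persons$weight[persons$heart_disease | persons$stroke])
    if (compute_costs && y_end >= 2012L)
      cost_mat[, k] <- cost_at(persons, y_end)

    # demographic ledger must close every cycle
    resid <- live_end[k] -
      (live_start[k] - sm$deaths - sm$ageouts + ent_w)
    if (abs(resid) > 1e-6 * max(1, live_end[k]))
      stop("run_projection: demographic ledger failed to close at ", y_end)
  }

  # annualized person-years: each cycle splits evenly across its two years
  ann_years <- seq(base$year + 1L, horizon)
  py_annual <- stats::setNames(numeric(length(ann_years)), ann_years)
  for (k in seq_len(K)) {
    yc <- as.character(c(years[k] - 1L, years[k]))
    py_annual[yc] <- py_annual[yc] + person_years[k] / 2
  }

  structure(list(scenario = scenario, seed = seed,
                 base_year = base$year, horizon = horizon,
                 years = years,
                 pop_total = pop_total, pop_by_band = pop_by_band,
                 cvd_pop = cvd_pop,
                 base_band = base_band, base_total = base_total,
                 deaths = deaths_w, deaths_cvd = deaths_cvd_w,
                 deaths_by_band = deaths_by_band,
                 deaths_cvd_by_band = deaths_cvd_by_band,
                 ageouts = ageouts_w, entrants = entrants_w,
                 live_start = live_start, live_end = live_end,
                 person_years = person_years,
                 person_years_annual = py_annual,
                 costs = cost_mat,
                 final_state = population_state(horizon, persons)),
            class = "cvd_projection")
}

#' Check the demographic ledger of a projection
#'
#' Verifies that live weight at each cycle end equals live weight at the
#' start minus deaths and age-110 exits plus entrants, and that consecutive
#' cycles chain.
#'
#' @param output a `cvd_projection`.
#' @param tol relative tolerance.
#' @return maximum relative residual, invisibly; errors if above `tol`.
#' @export
check_ledger <- function(output, tol = 1e-6) {
  resid <- abs(output$live_end -
                 (output$live_start - output$deaths - output$ageouts +
                    output$entrants)) / pmax(1, output$live_end)
  K <- length(output$years)
  chain <- if (K > 1)
    abs(output$live_start[-1] - output$live_end[-K]) /
      pmax(1, output$live_end[-K]) else 0
  worst <- max(resid, chain)
  if (worst > tol) stop("check_ledger: ledger residual ", worst, " > ", tol)
  invisible(worst)
}

#' Age-adjusted CVD death rate
#'
#' Directly standardized death rate of persons with lagged heart disease or
#' stroke: for each requested year, the weighted average over age bands of
#' (CVD deaths in the two-year cycle ending that year) / (total live
#' population in the band), using a fixed reference age distribution.  The
#' denominator is total population, not the CVD population.  The default
#' reference is the projection's own 2012 population in 5-year bands.
#'
#' @param output a `cvd_projection`.
#' @param years years at which to evaluate (cycle boundaries).
#' @param reference optional reference band weights summing to 1.
#' @return named vector of standardized rates.
#' @export
age_adjusted_cvd_death_rate <- function(output, years = output$years,
                                        reference = NULL) {
  # 5-year bands with an open-ended 85+ terminal band, so sparse very-old
  # bands cannot leave the standard undefined at moderate sample sizes
  collapse <- function(v) c(v[1:11], `85+` = sum(v[12:N_AGE_BANDS]))
  if (is.null(reference)) {
    k12 <- match(2012L, output$years)
    if (is.na(k12)) stop("age_adjusted_cvd_death_rate: 2012 not in projection")
    reference <- collapse(output$pop_by_band[, k12])
    reference <- reference / sum(reference)
  }
  vapply(as.character(years), function(y) {
    k <- match(as.integer(y), output$years)
    if (is.na(k)) stop("age_adjusted_cvd_death_rate: year ", y,
                       " outside projection")
    pop <- collapse(output$pop_by_band[, k])
    deaths <- collapse(output$deaths_cvd_by_band[, k])
    rates <- ifelse(pop > 0, deaths / pop, NA_real_)
    names(rates) <- names(pop)
    direct_standardized_rate(rates, reference)
  }, numeric(1))
}

#' Achieved reduction in the age-adjusted CVD death rate
#'
#' `1 - rate(window[2]) / rate(window[1])`, measured against the run's own
#' starting rate.
#'
#' @param output a `cvd_projection`.
#' @param window two cycle-boundary years, default `c(2012, 2024)`.
#' @param reference optional reference band weights.
#' @return the achieved fractional reduction.
#' @export
cvd_rate_reduction <- function(output, window = c(2012L, 2024L),
                               reference = NULL) {
  r <- age_adjusted_cvd_death_rate(output, window, reference)
  unname(1 - r[2] / r[1])
}

#' @export
print.cvd_projection <- function(x, ...) {
  cat("<cvd_projection>", x$scenario$type, "scenario, seed", x$seed, "\n")
  cat("  ", x$base_year, "->", x$horizon, ": population",
      format(round(x$base_total), big.mark = ","), "->",
      format(round(x$pop_total[length(x$pop_total)]), big.mark = ","), "\n")
  invisible(x)
}

#' Summarize a projection
#' @param object a `cvd_projection`.
#' @param ... unused.
#' @return data frame of per-year key aggregates.
#' @export
summary.cvd_projection <- function(object, ...) {
  df <- data.frame(year = object$years,
                   population = as.numeric(object$pop_total),
                   cvd_population = as.numeric(object$cvd_pop),
                   deaths = as.numeric(object$deaths),
                   cvd_deaths = as.numeric(object$deaths_cvd),
                   person_years = as.numeric(object$person_years))
  for (cat in COST_CATEGORIES) df[[cat]] <- as.numeric(object$costs[cat, ])
  df
}

#' Plot projection trajectories
#'
#' Base-graphics panels of the represented population and (when available)
#' the cost indices normalized to 100 at 2012.
#'
#' @param x a `cvd_projection`.
#' @param ... passed to [plot()].
#' @export
plot.cvd_projection <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$years, x$pop_total / 1e6, type = "l", xlab = "year",
       ylab = "population (millions)", main = "Represented population", ...)
  if (any(is.finite(x$costs))) {
    k12 <- match(2012L, x$years)
    idx <- t(apply(x$costs, 1, function(v) 100 * v / v[k12]))
    ok <- x$years >= 2012
    graphics::matplot(x$years[ok], t(idx[, ok]), type = "l", lty = 1,
                      xlab = "year", ylab = "index (2012 = 100)",
                      main = "Cost indices")
    graphics::legend("topleft", legend = rownames(idx), col = 1:3, lty = 1,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Tidy per-year metrics of a projection
#'
#' Long-format data frame `(year, metric, scenario, value)` suitable for
#' CSV export.
#'
#' @param output a `cvd_projection`.
#' @return a data frame.
#' @export
projection_metrics <- function(output) {
  df <- summary(output)
  long <- do.call(rbind, lapply(setdiff(names(df), "year"), function(m)
    data.frame(year = df$year, metric = m,
               scenario = output$scenario$type, value = df[[m]])))
  long[!is.na(long$value), ]
}
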
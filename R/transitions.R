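#' Transition probability for persons
#'
#' Evaluates `clamp(multiplier * scale * cloglog_prob(x %*% beta), 0, 1)`
#' for one outcome over one or more persons, using their *lagged*
#' (start-of-cycle) state.  A multiplier of 1 reproduces the unmodified
#' model; scenario multipliers act on the probability scale with clamping.
#'
#' @param persons a data frame of persons or a `population_state`.
#' @param outcome outcome name present in `models`.
#' @param models a `transition_model_set`.
#' @param multiplier positive scenario multiplier.
#' @return numeric vector of probabilities.
#' @export
transition_probability <- function(persons, outcome, models, multiplier = 1) {
  if (inherits(persons, "population_state")) persons <- persons$persons
  if (!outcome %in% names(models$models))
    stop("transition_probability: unknown outcome '", outcome, "'")
  if (length(multiplier) != 1 || multiplier <= 0)
    stop("transition_probability: multiplier must be positive")
  m <- models$models[[outcome]]
  eta <- clamp(as.numeric(design_matrix(persons, m$covariates) %*% m$coef),
               -30, 30)
  clamp(multiplier * m$scale * cloglog_prob(eta), 0, 1)
}

# probability without the positivity check on multiplier (internal; allows
# multiplier 0 used by degenerate tests and scenario machinery).
prob_for <- function(persons, outcome, models, multiplier = 1) {
  m <- models$models[[outcome]]
  if (is.null(m)) stop_config("missing transition model for '", outcome, "'")
  eta <- clamp(as.numeric(design_matrix(persons, m$covariates) %*% m$coef),
               -30, 30)
  clamp(multiplier * m$scale * cloglog_prob(eta), 0, 1)
}

# One two-year cycle of joint transitions, evaluated from the lagged state
# only.  Draw order is fixed (death, incidences in DISEASES order, LTC,
# smoking start, smoking quit) and every draw covers all persons alive at
# the cycle start, so common random numbers align across scenarios.
# Death pre-empts recording of same-cycle incident events.
#
# multipliers: list(death_all, death_cvd, incidence = named list)
cycle_step <- function(persons, models, multipliers = list(), seed,
                       record_events = FALSE) {
  alive_idx <- which(persons$alive)
  la <- persons[alive_idx, , drop = FALSE]
  n <- nrow(la)
  if (n == 0L)
    return(list(persons = persons, summary = empty_cycle_summary(),
                events = NULL))
  set.seed(seed)

  m_all <- multipliers$death_all %||% 1
  m_cvd <- multipliers$death_cvd %||% 1
  m_inc <- multipliers$incidence %||% list()

  has_cvd_lag <- la$heart_disease | la$stroke
  p_death <- prob_for(la, "death", models, 1) * m_all *
    ifelse(has_cvd_lag, m_cvd, 1)
  p_death <- clamp(p_death, 0, 1)
  died <- stats::runif(n) < p_death

  incident <- list()
  at_risk <- list()
  for (d in DISEASES) {
    ar <- !la[[d]]
    p <- prob_for(la, paste0("inc_", d), models, m_inc[[d]] %||% 1)
    u <- stats::runif(n)
    incident[[d]] <- ar & u < p & !died
    at_risk[[d]] <- ar
  }
  ar_ltc <- !la$in_ltc
  ltc_event <- ar_ltc & stats::runif(n) < prob_for(la, "ltc_admission", models) &
    !died
  ar_start <- !la$smoker
  start_event <- ar_start & stats::runif(n) <
    prob_for(la, "smoking_start", models) & !died
  ar_quit <- la$smoker
  quit_event <- ar_quit & stats::runif(n) <
    prob_for(la, "smoking_quit", models) & !died

  events <- NULL
  if (record_events) {
    events <- la[, c("person_id", "age", "sex", "education", "immigrant",
                     DISEASES, "smoker", "obese", "activity_limited",
                     "cognitively_impaired", "in_ltc", "weight")]
    events$death <- died
    for (d in DISEASES) {
      events[[paste0("event_", d)]] <- incident[[d]]
      events[[paste0("at_risk_", d)]] <- at_risk[[d]]
    }
    events$event_ltc <- ltc_event; events$at_risk_ltc <- ar_ltc
    events$event_smoking_start <- start_event
    events$at_risk_smoking_start <- ar_start
    events$event_smoking_quit <- quit_event
    events$at_risk_smoking_quit <- ar_quit
  }

  # update state: disease flags are absorbing; ages advance 2 years
  new_age <- la$age + 2L
  surv <- !died & new_age <= MAX_AGE
  aged_out <- !died & new_age > MAX_AGE

  upd <- la
  upd$age <- new_age
  for (d in DISEASES) upd[[d]] <- la[[d]] | incident[[d]]
  upd$cognitively_impaired <- upd$cognitively_impaired | incident$dementia
  upd$in_ltc <- upd$in_ltc | ltc_event
  upd$smoker <- (la$smoker & !quit_event) | start_event
  upd$alive <- surv

  w <- la$weight
  end_band <- age_band_index(pmin(new_age, MAX_AGE))
  smry <- list(
    live_start = sum(w),
    deaths = sum(w[died]),
    deaths_cvd = sum(w[died & has_cvd_lag]),
    ageouts = sum(w[aged_out]),
    deaths_by_band = band_sum(pmin(new_age, MAX_AGE)[died], w[died]),
    deaths_cvd_by_band = band_sum(pmin(new_age, MAX_AGE)[died & has_cvd_lag],
                                  w[died & has_cvd_lag]),
    # survivors and age-outs live the full cycle, decedents half of it
    person_years = 2 * sum(w[surv]) + 2 * sum(w[aged_out]) + 1 * sum(w[died])
  )

  persons[alive_idx, ] <- upd
  list(persons = persons, summary = smry, events = events)
}

empty_cycle_summary <- function() {
  list(live_start = 0, deaths = 0, deaths_cvd = 0, ageouts = 0,
       deaths_by_band = band_sum(integer(), numeric()),
       deaths_cvd_by_band = band_sum(integer(), numeric()),
       person_years = 0)
}

#' Apply one cycle of transitions to a population
#'
#' Advances a [population_state()] by one two-year cycle: death, disease
#' incidence (among those at risk), long-term-care admission and smoking
#' changes are drawn jointly from the lagged state.  Disease flags are
#' absorbing; dead persons are retained with `alive = FALSE`; persons
#' exceeding age 110 exit.  Fully reproducible from `rng_seed`.
#'
#' @param state a `population_state`.
#' @param models a `transition_model_set`.
#' @param multipliers list with optional entries `death_all`, `death_cvd`
#'   (applied to persons with lagged heart disease or stroke) and
#'   `incidence` (named list of per-disease multipliers).  Multipliers act
#'   on the probability scale and are clamped to \[0, 1\].
#' @param rng_seed integer seed.
#' @return the next `population_state`, two years later.
#' @export
apply_transitions <- function(state, models, multipliers = list(),
                              rng_seed = 1L) {
  step <- cycle_step(state$persons, models, multipliers, rng_seed)
  out <- structure(list(year = state$year + 2L, persons = step$persons,
                        cycle_length = state$cycle_length),
                   class = "population_state")
  attr(out, "cycle_summary") <- step$summary
  out
}

#' Simulate a longitudinal estimation panel
#'
#' Runs the population forward `n_cycles` two-year cycles under the true
#' parameters, recording one row per person-cycle with the lagged
#' covariates, at-risk indicators and incident-outcome indicators needed
#' for cloglog estimation.  Incident outcomes are recorded only among
#' persons at risk (flag not yet set); dead persons exit the panel.
#' Emulates a biennial longitudinal health survey.
#'
#' @param pop a `population_state` (the panel's wave-1 sample).
#' @param truth a `synthetic_truth`.
#' @param n_cycles number of two-year cycles (>= 1).
#' @param seed integer seed.
#' @return a data frame of person-cycle records (class `msim_panel`) with
#'   derived covariate columns (`age_c`, `male`, ...) ready for fitting.
#' @export
simulate_panel <- function(pop, truth, n_cycles, seed = 1L) {
  if (length(n_cycles) != 1 || n_cycles < 1)
    stop("simulate_panel: n_cycles must be >= 1")
  persons <- pop$persons[pop$persons$alive, , drop = FALSE]
  if (nrow(persons) == 0L) stop("simulate_panel: empty population")
  rows <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    step <- cycle_step(persons, truth$transitions, list(),
                       substream(seed, k), record_events = TRUE)
    ev <- step$events
    ev$cycle <- k
    ev$year <- pop$year + 2L * (k - 1L)
    rows[[k]] <- ev
    persons <- step$persons[step$persons$alive, , drop = FALSE]
    if (nrow(persons) == 0L) {
      rows <- rows[seq_len(k)]
      break
    }
  }
  panel <- do.call(rbind, rows)
  panel <- add_covariate_columns(panel)
  class(panel) <- c("msim_panel", "data.frame")
  panel
}

# outcome name -> (event column, at-risk filter) on a panel
panel_outcome_columns <- function(outcome) {
  if (outcome == "death") list(event = "death", at_risk = NULL)
  else if (startsWith(outcome, "inc_")) {
    d <- sub("^inc_", "", outcome)
    list(event = paste0("event_", d), at_risk = paste0("at_risk_", d))
  } else if (outcome == "ltc_admission")
    list(event = "event_ltc", at_risk = "at_risk_ltc")
  else if (outcome == "smoking_start")
    list(event = "event_smoking_start", at_risk = "at_risk_smoking_start")
  else if (outcome == "smoking_quit")
    list(event = "event_smoking_quit", at_risk = "at_risk_smoking_quit")
  else stop("unknown outcome '", outcome, "'")
}

#' Refit every transition model on a panel
#'
#' Re-estimates the coefficient vector of each outcome in `models` by
#' [fit_cloglog()] on the at-risk person-cycle records of `panel`, keeping
#' the covariate lists and dependency structure fixed.  Outcomes whose
#' at-risk records hold no events (or no non-events) raise an estimation
#' error unless `skip_failures` is set, in which case the previous
#' coefficients are retained and the failure recorded.
#'
#' @param panel an `msim_panel`.
#' @param models a `transition_model_set` providing the specification.
#' @param skip_failures keep prior coefficients when a refit fails.
#' @return a list with `models` (refitted `transition_model_set`), `fits`
#'   (per-outcome `cloglog_fit` objects) and `failed` (character).
#' @export
fit_transition_models <- function(panel, models, skip_failures = FALSE) {
  fits <- list()
  failed <- character()
  new_models <- models$models
  for (nm in names(models$models)) {
    m <- models$models[[nm]]
    cols <- panel_outcome_columns(nm)
    dat <- panel
    if (!is.null(cols$at_risk))
      dat <- dat[as.logical(dat[[cols$at_risk]]), , drop = FALSE]
    dat$.y <- as.numeric(dat[[cols$event]])
    form <- stats::reformulate(if (length(m$covariates)) m$covariates else "1",
                               response = ".y")
    fit <- tryCatch(fit_cloglog(form, dat), error = function(e) e)
    if (inherits(fit, "error")) {
      if (!skip_failures) stop("fit_transition_models: ", nm, ": ",
                               conditionMessage(fit))
      failed <- c(failed, nm)
    } else {
      fits[[nm]] <- fit
      cf <- stats::coef(fit)
      names(cf)[1] <- "(Intercept)"
      new_models[[nm]] <- transition_model(nm, m$covariates,
                                           cf[names(m$coef)], m$scale)
    }
  }
  list(models = transition_model_set(unname(new_models)), fits = fits,
       failed = failed)
}
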
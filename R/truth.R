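#' Transition model objects
#'
#' A `transition_model` holds the outcome name, the covariate list (drawn
#' from a fixed vocabulary of lagged person fields and age transforms), the
#' cloglog coefficient vector, an optional probability-scale `scale`
#' multiplier, and the list of lagged diseases allowed to enter (the
#' dependency graph edge list).  Only lagged states feed transitions, so
#' the within-cycle graph is acyclic by construction.
#'
#' @param outcome outcome name (e.g. `"death"`, `"inc_heart_disease"`).
#' @param covariates character vector from the covariate vocabulary.
#' @param coef named coefficients: `"(Intercept)"` plus one per covariate.
#' @param scale probability-scale multiplier (>= 0), default 1.
#' @return a `transition_model`.
#' @export
transition_model <- function(outcome, covariates, coef, scale = 1) {
  bad <- setdiff(covariates, COVARIATE_VOCAB)
  if (length(bad))
    stop_config("unknown covariates for ", outcome, ": ",
                paste(bad, collapse = ", "))
  want <- c("(Intercept)", covariates)
  if (!setequal(names(coef), want))
    stop_config("coefficients for ", outcome,
                " must be named (Intercept) + covariates")
  if (scale < 0) stop_config("scale for ", outcome, " must be >= 0")
  structure(list(outcome = outcome, covariates = covariates,
                 coef = coef[want], scale = scale,
                 depends = intersect(covariates, DISEASES)),
            class = "transition_model")
}

#' Bundle transition models into a set
#' @param models list of [transition_model()] objects.
#' @return a `transition_model_set` keyed by outcome name.
#' @export
transition_model_set <- function(models) {
  names(models) <- vapply(models, `[[`, "", "outcome")
  structure(list(models = models), class = "transition_model_set")
}

#' @export
print.transition_model_set <- function(x, ...) {
  cat("<transition_model_set>", length(x$models), "outcomes:\n ",
      paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

# Design matrix over the covariate vocabulary.  Age is centered at 60 and
# scaled per decade; age_c2 is its square.
design_matrix <- function(persons, covariates) {
  n <- nrow(persons)
  if (!length(covariates))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cols <- lapply(covariates, function(v) {
    switch(v,
      age_c = (persons$age - 60) / 10,
      age_c2 = ((persons$age - 60) / 10)^2,
      male = as.numeric(persons$sex == "male"),
      education2 = as.numeric(persons$education >= 2L),
      education3 = as.numeric(persons$education == 3L),
      as.numeric(persons[[v]]))
  })
  X <- cbind(`(Intercept)` = rep(1, n),
             matrix(unlist(cols), nrow = n,
                    dimnames = list(NULL, covariates)))
  X
}

# Add the derived covariate columns to a data frame (used when fitting on
# panel data with formulas).
add_covariate_columns <- function(df) {
  for (v in names(df))  # keep model.matrix from renaming logical dummies
    if (is.logical(df[[v]])) df[[v]] <- as.numeric(df[[v]])
  df$age_c <- (df$age - 60) / 10
  df$age_c2 <- df$age_c^2
  df$male <- as.numeric(df$sex == "male")
  df$education2 <- as.numeric(df$education >= 2L)
  df$education3 <- as.numeric(df$education == 3L)
  df
}

#' Cost model set
#'
#' Two-part utilization models per category: a participation equation
#' (declared link, logistic by default) for any use, and a log-linear
#' positive-part mean, plus the unit cost per visit/night in 2012 C$.
#'
#' @param categories named list; each entry has `participation` (list with
#'   `link`, `covariates`, `coef`), `intensity` (list with `covariates`,
#'   `coef`), and `unit_cost`.
#' @return a `cost_model_set`.
#' @export
cost_model_set <- function(categories) {
  for (nm in names(categories)) {
    cc <- categories[[nm]]
    if (is.null(cc$unit_cost) || cc$unit_cost <= 0)
      stop_config("cost model ", nm, ": unit_cost must be positive")
    if (!cc$participation$link %in% c("logit", "cloglog"))
      stop_config("cost model ", nm, ": link must be logit or cloglog")
  }
  structure(list(categories = categories), class = "cost_model_set")
}

default_transition_models <- function(config) {
  m <- list(
    # Incidence intercepts are set so the cumulative incident risk over a
    # lifetime, net of the excess mortality of prevalent cases, roughly
    # reproduces the cross-sectional age-prevalence profiles of the base
    # population: prevalence then drifts mildly upward over the
    # projection (composition effect) rather than exploding.
    transition_model("death",
      c("age_c", "age_c2", "male", "smoker", DISEASES),
      c(`(Intercept)` = -5.00, age_c = 0.87, age_c2 = 0.02, male = 0.45,
        smoker = 0.40, diabetes = 0.35, hypertension = 0.10, stroke = 0.60,
        cancer = 0.40, heart_disease = 0.50, lung_disease = 0.30,
        dementia = 0.60)),
    transition_model("inc_hypertension",
      c("age_c", "age_c2", "obese", "male"),
      c(`(Intercept)` = -3.65, age_c = 0.35, age_c2 = -0.06, obese = 0.50,
        male = 0.10)),
    transition_model("inc_diabetes",
      c("age_c", "age_c2", "obese", "male"),
      c(`(Intercept)` = -4.72, age_c = 0.45, age_c2 = -0.08, obese = 0.80,
        male = 0.15)),
    transition_model("inc_heart_disease",
      c("age_c", "age_c2", "male", "smoker", "obese", "hypertension",
        "diabetes"),
      c(`(Intercept)` = -4.95, age_c = 0.55, age_c2 = -0.08, male = 0.40,
        smoker = 0.50, obese = 0.20, hypertension = 0.55, diabetes = 0.45)),
    transition_model("inc_stroke",
      c("age_c", "age_c2", "male", "smoker", "hypertension", "diabetes",
        "heart_disease"),
      c(`(Intercept)` = -5.98, age_c = 0.65, age_c2 = -0.10, male = 0.20,
        smoker = 0.40, hypertension = 0.60, diabetes = 0.40,
        heart_disease = 0.50)),
    transition_model("inc_cancer",
      c("age_c", "age_c2", "smoker", "male"),
      c(`(Intercept)` = -4.68, age_c = 0.45, age_c2 = -0.08, smoker = 0.40,
        male = 0.10)),
    transition_model("inc_lung_disease",
      c("age_c", "age_c2", "smoker"),
      c(`(Intercept)` = -5.22, age_c = 0.45, age_c2 = -0.08, smoker = 0.90)),
    transition_model("inc_dementia",
      c("age_c", "age_c2", "stroke"),
      c(`(Intercept)` = -5.30, age_c = 1.00, age_c2 = -0.10, stroke = 0.70)),
    transition_model("ltc_admission",
      c("age_c", "dementia", "activity_limited", "stroke"),
      c(`(Intercept)` = -6.20, age_c = 0.70, dementia = 1.50,
        activity_limited = 0.80, stroke = 0.50)),
    transition_model("smoking_start",
      c("age_c"),
      c(`(Intercept)` = -4.50, age_c = -0.30)),
    transition_model("smoking_quit",
      c("age_c"),
      c(`(Intercept)` = -1.70, age_c = 0.10))
  )
  transition_model_set(m)
}

default_cost_models <- function(config) {
  uc <- config$costs$unit_costs
  cost_model_set(list(
    generalist_visits = list(
      participation = list(link = "logit",
        covariates = c("age_c", DISEASES),
        coef = c(`(Intercept)` = 1.27, age_c = 0.15, diabetes = 0.40,
                 hypertension = 0.30, stroke = 0.40, cancer = 0.40,
                 heart_disease = 0.50, lung_disease = 0.40, dementia = 0.30)),
      intensity = list(
        covariates = c("age_c", DISEASES),
        coef = c(`(Intercept)` = 1.25, age_c = 0.08, diabetes = 0.25,
                 hypertension = 0.15, stroke = 0.30, cancer = 0.30,
                 heart_disease = 0.35, lung_disease = 0.30, dementia = 0.20)),
      unit_cost = unname(uc["generalist_visits"])),
    specialist_visits = list(
      participation = list(link = "logit",
        covariates = c("age_c", DISEASES),
        coef = c(`(Intercept)` = 0.00, age_c = 0.20, diabetes = 0.40,
                 hypertension = 0.20, stroke = 0.50, cancer = 0.80,
                 heart_disease = 0.70, lung_disease = 0.40, dementia = 0.20)),
      intensity = list(
        covariates = c("age_c", DISEASES),
        coef = c(`(Intercept)` = 1.03, age_c = 0.05, diabetes = 0.20,
                 hypertension = 0.10, stroke = 0.30, cancer = 0.50,
                 heart_disease = 0.40, lung_disease = 0.25, dementia = 0.15)),
      unit_cost = unname(uc["specialist_visits"])),
    hospital_nights = list(
      participation = list(link = "logit",
        covariates = c("age_c", "age_c2", "in_ltc", DISEASES),
        coef = c(`(Intercept)` = -2.44, age_c = 0.45, age_c2 = 0.05,
                 in_ltc = 0.50, diabetes = 0.40, hypertension = 0.20,
                 stroke = 1.10, cancer = 0.80, heart_disease = 1.00,
                 lung_disease = 0.60, dementia = 0.70)),
      intensity = list(
        covariates = c("age_c", DISEASES),
        coef = c(`(Intercept)` = 1.95, age_c = 0.15, diabetes = 0.10,
                 hypertension = 0.05, stroke = 0.50, cancer = 0.25,
                 heart_disease = 0.30, lung_disease = 0.20, dementia = 0.60)),
      unit_cost = unname(uc["hospital_nights"]))
  ))
}

#' Generate the synthetic "true" parameter sets
#'
#' Builds the complete transition and cost model sets that stand in for the
#' confidential estimation inputs: a two-year mortality schedule rising
#' strictly with age (Gompertz-type, intercept set so period life
#' expectancy at 65 sits near observed Canadian levels), excess death
#' hazards for heart disease and stroke, incidence models with the
#' clinically motivated lagged-disease dependency graph, two-part cost
#' models, and the exogenous annual mortality-improvement rate.
#'
#' @param seed integer recorded as `generation_seed` (the mapping from
#'   config to parameters is deterministic).
#' @param config settings from [default_config()]; the components
#'   `mortality_improvement` and `excess_death` (optional named overrides
#'   for the heart-disease/stroke death coefficients) are consumed here.
#' @return an object of class `synthetic_truth` with elements
#'   `transitions`, `costs`, `mortality_improvement`, `generation_seed`,
#'   `config`.
#' @export
make_true_parameters <- function(seed = 1L, config = default_config()) {
  validate_config(config)
  tm <- default_transition_models(config)
  if (!is.null(config$excess_death)) {
    for (d in names(config$excess_death)) {
      v <- config$excess_death[[d]]
      if (v < 0) stop_config("excess_death$", d, ": must be >= 0")
      tm$models$death$coef[[d]] <- v
    }
  }
  dc <- tm$models$death$coef
  if (dc[["age_c"]] <= 0 || dc[["age_c2"]] < 0 ||
      dc[["age_c"]] + 2 * dc[["age_c2"]] * (MIN_AGE - 60) / 10 <= 0)
    stop_config("death model: hazard must increase strictly with age")
  if (config$mortality_improvement < 0 || config$mortality_improvement >= 1)
    stop_config("mortality_improvement: must be in [0, 1)")
  structure(list(transitions = tm,
                 costs = default_cost_models(config),
                 mortality_improvement = config$mortality_improvement,
                 generation_seed = as.integer(seed),
                 config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> seed", x$generation_seed, "-",
      length(x$transitions$models), "transition outcomes,",
      length(x$costs$categories), "cost categories\n")
  invisible(x)
}

#' Population-implied two-year mortality schedule
#'
#' Evaluates the death model on a population and averages the two-year
#' death probability by single year of age (weighted); ages not present are
#' filled by linear interpolation/extrapolation of the log-integrated
#' hazard.  Used as input to [period_life_expectancy()].
#'
#' @param truth a `synthetic_truth`.
#' @param state a `population_state`.
#' @return named numeric vector of 2-year death probabilities for ages
#'   30..109.
#' @export
implied_mortality_schedule <- function(truth, state) {
  p <- state$persons[state$persons$alive, , drop = FALSE]
  m <- truth$transitions$models$death
  eta <- as.numeric(design_matrix(p, m$covariates) %*% m$coef)
  q <- clamp(m$scale * cloglog_prob(clamp(eta, -30, 30)), 0, 1)
  ages <- MIN_AGE:(MAX_AGE - 1L)
  qbar <- vapply(ages, function(a) {
    sel <- p$age == a
    if (any(sel)) sum(q[sel] * p$weight[sel]) / sum(p$weight[sel]) else NA_real_
  }, numeric(1))
  # fill gaps on the log cumulative-hazard scale
  lh <- log(-log(1 - pmin(qbar, 0.999)))
  ok <- which(is.finite(lh))
  lh <- stats::approx(ages[ok], lh[ok], xout = ages, rule = 2)$y
  out <- clamp(1 - exp(-exp(lh)), 0, 0.999)
  names(out) <- ages
  out
}

#' Serialize a transition model set to JSON
#'
#' Outcome -> covariate names, coefficients, probability scale and lagged
#' disease dependency list; round-trips losslessly through
#' [read_model_set()].
#'
#' @param models a `transition_model_set`.
#' @param path JSON file path.
#' @return `read_model_set()` returns a `transition_model_set`.
#' @export
write_model_set <- function(models, path) {
  payload <- lapply(models$models, function(m)
    list(outcome = m$outcome, covariates = m$covariates,
         coef = as.list(m$coef), scale = m$scale, depends = m$depends))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_set
#' @export
read_model_set <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  transition_model_set(lapply(payload, function(m)
    transition_model(m$outcome, unlist(m$covariates) %||% character(),
                     unlist(m$coef), m$scale)))
}
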
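#' Expected annual healthcare use per person
#'
#' Two-part expectation `P(use > 0) * E[count | use > 0]` for one resource
#' category, evaluated on the current person state.  The participation part
#' uses its declared link (logistic by default); the positive part has a
#' log-linear (multiplicative) mean.
#'
#' @param persons data frame of persons or a `population_state`.
#' @param category one of `hospital_nights`, `specialist_visits`,
#'   `generalist_visits`.
#' @param costs a `cost_model_set`.
#' @return non-negative expected annual counts.
#' @export
expected_use <- function(persons, category, costs) {
  if (inherits(persons, "population_state")) persons <- persons$persons
  cc <- costs$categories[[category]]
  if (is.null(cc)) stop("expected_use: unknown category '", category, "'")
  eta_p <- clamp(as.numeric(design_matrix(persons, cc$participation$covariates)
                            %*% cc$participation$coef), -30, 30)
  p <- if (cc$participation$link == "logit") stats::plogis(eta_p)
       else cloglog_prob(eta_p)
  mu <- exp(clamp(as.numeric(design_matrix(persons, cc$intensity$covariates)
                             %*% cc$intensity$coef), -30, 30))
  p * mu
}

#' Cumulative structural cost growth factor
#'
#' Residual ("structural") real cost growth beyond demographic and health
#' drivers: the cumulative product of `(1 + annual rate)` from
#' `base_year + 1` through `year`, with the declining default schedule
#' 1.5\% for 2013-2018, 1\% for 2019-2028, 0.5\% for 2029-2038, 0\%
#' thereafter.  The factor at `base_year` is 1.
#'
#' @param year calendar year (scalar or vector), `>= base_year`.
#' @param schedule list with `breaks` (segment start years) and `rates`.
#' @param base_year normalization year (default 2012).
#' @return multiplicative factor(s).
#' @export
#' @examples
#' structural_growth_factor(2015, default_config()$growth_schedule)  # 1.015^3
structural_growth_factor <- function(year,
                                     schedule = default_config()$growth_schedule,
                                     base_year = 2012L) {
  if (any(year < base_year))
    stop("structural_growth_factor: year before base_year")
  rate_in <- function(y) {
    # rate applying to calendar year y: segment i covers
    # (breaks[i], breaks[i+1]]; beyond the last break the last rate holds.
    i <- findInterval(y - 1L, schedule$breaks)
    ifelse(i < 1, 0, schedule$rates[pmin(i, length(schedule$rates))])
  }
  vapply(year, function(yy) {
    if (yy == base_year) return(1)
    prod(1 + rate_in((base_year + 1L):yy))
  }, numeric(1))
}

#' Aggregate annual healthcare costs of a population
#'
#' Per-category weighted dollars over live persons:
#' `sum(weight * expected_use * unit_cost) * growth_factor(year)`, with the
#' configured share of each physician category's cost (consultations taking
#' place in a hospital setting) folded into the hospitalization category.
#'
#' @param state a `population_state` with `state$year == year`.
#' @param costs a `cost_model_set`.
#' @param schedule structural growth schedule.
#' @param year calendar year of the costs.
#' @param hospital_share named shares of `specialist_visits` and
#'   `generalist_visits` cost attributed to the hospital setting.
#' @param growth_base_year base year of the growth schedule.
#' @return named vector of dollars for `hospital_nights`,
#'   `specialist_visits`, `generalist_visits`.
#' @export
aggregate_costs <- function(state, costs,
                            schedule = default_config()$growth_schedule,
                            year = state$year,
                            hospital_share = c(specialist_visits = 0.30,
                                               generalist_visits = 0.10),
                            growth_base_year = 2012L) {
  if (state$year != year)
    stop("aggregate_costs: state year ", state$year, " != ", year)
  live <- state$persons[state$persons$alive, , drop = FALSE]
  g <- structural_growth_factor(max(year, growth_base_year), schedule,
                                growth_base_year)
  raw <- vapply(COST_CATEGORIES, function(cat) {
    if (nrow(live) == 0L) return(0)
    uc <- costs$categories[[cat]]$unit_cost
    sum(live$weight * expected_use(live, cat, costs)) * uc * g
  }, numeric(1))
  ss <- hospital_share[["specialist_visits"]]
  sg <- hospital_share[["generalist_visits"]]
  out <- c(hospital_nights = unname(raw["hospital_nights"] +
                                      ss * raw["specialist_visits"] +
                                      sg * raw["generalist_visits"]),
           specialist_visits = unname((1 - ss) * raw["specialist_visits"]),
           generalist_visits = unname((1 - sg) * raw["generalist_visits"]))
  out
}

#' Normalize a cost series to an index
#'
#' `index(year) = 100 * series(year) / base_value`.  Scenario series should
#' be normalized to the *baseline scenario's* base-year value so indices
#' are comparable across scenarios.
#'
#' @param series named numeric vector (names are years) of dollars.
#' @param base_year base year (informational).
#' @param base_value positive dollars at the base year.
#' @return named index vector (100 at the base value).
#' @export
normalize_index <- function(series, base_year, base_value) {
  if (length(base_value) != 1 || !is.finite(base_value) || base_value <= 0)
    stop("normalize_index: base_value must be positive")
  100 * series / base_value
}

#' Simulate observed annual healthcare use
#'
#' Draws use from the two-part truth: participation Bernoulli, and for
#' participants a count `1 + Poisson(mu - 1)` whose conditional mean equals
#' the model's `mu` exactly.  Used to generate administrative-style
#' utilization records for estimation tests.
#'
#' @param persons data frame of persons or `population_state`.
#' @param costs a `cost_model_set`.
#' @param seed integer seed.
#' @return data frame with `person_id` and one count column per category.
#' @export
simulate_use <- function(persons, costs, seed = 1L) {
  if (inherits(persons, "population_state"))
    persons <- persons$persons[persons$persons$alive, , drop = FALSE]
  set.seed(substream(seed, 17L))
  out <- data.frame(person_id = persons$person_id)
  for (cat in names(costs$categories)) {
    cc <- costs$categories[[cat]]
    eta_p <- clamp(as.numeric(design_matrix(persons, cc$participation$covariates)
                              %*% cc$participation$coef), -30, 30)
    p <- if (cc$participation$link == "logit") stats::plogis(eta_p)
         else cloglog_prob(eta_p)
    mu <- exp(clamp(as.numeric(design_matrix(persons, cc$intensity$covariates)
                               %*% cc$intensity$coef), -30, 30))
    use <- stats::runif(nrow(persons)) < p
    cnt <- integer(nrow(persons))
    cnt[use] <- 1L + stats::rpois(sum(use), pmax(mu[use] - 1, 0))
    out[[cat]] <- cnt
  }
  out
}

#' Fit a two-part utilization model
#'
#' Standard two-part estimation: a logistic participation equation for any
#' use and a log-linear positive-part mean fitted by Poisson
#' quasi-likelihood on the positive counts (consistent for the conditional
#' mean whatever the count distribution).
#'
#' @param use_counts integer vector of observed annual counts.
#' @param persons data frame of persons aligned with `use_counts`.
#' @param covariates covariate names (participation and intensity share the
#'   list here).
#' @param unit_cost unit cost attached to the refitted category.
#' @return a category entry usable inside [cost_model_set()].
#' @export
fit_two_part <- function(use_counts, persons, covariates, unit_cost = 1) {
  df <- add_covariate_columns(persons)
  df$.y <- as.numeric(use_counts > 0)
  form_p <- stats::reformulate(covariates, response = ".y")
  fit_p <- stats::glm(form_p, data = df, family = stats::binomial("logit"))
  pos <- df[use_counts > 0, , drop = FALSE]
  pos$.cnt <- use_counts[use_counts > 0]
  form_i <- stats::reformulate(covariates, response = ".cnt")
  fit_i <- stats::glm(form_i, data = pos, family = stats::poisson())
  fix_names <- function(cf) { names(cf)[1] <- "(Intercept)"; cf }
  list(participation = list(link = "logit", covariates = covariates,
                            coef = fix_names(stats::coef(fit_p))),
       intensity = list(covariates = covariates,
                        coef = fix_names(stats::coef(fit_i))),
       unit_cost = unit_cost)
}
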
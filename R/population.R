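#' Population state container
#'
#' A weighted cross-section of simulated persons at one calendar year
#' (a two-year cycle boundary).  Persons are rows of a data frame with the
#' documented columns; dead persons may be carried with `alive = FALSE` and
#' contribute nothing to aggregates.
#'
#' @param year calendar year of the snapshot.
#' @param persons data frame of persons (see [make_base_population()]).
#' @param cycle_length cycle length in years (fixed at 2).
#' @return an object of class `population_state`.
#' @export
population_state <- function(year, persons, cycle_length = 2L) {
  stopifnot(is.data.frame(persons))
  live <- persons[persons$alive, , drop = FALSE]
  if (nrow(live)) {
    if (any(live$age < MIN_AGE | live$age > MAX_AGE))
      stop("population_state: live persons must have age in [", MIN_AGE,
           ", ", MAX_AGE, "]")
    if (any(live$weight <= 0))
      stop("population_state: weights must be positive")
  }
  structure(list(year = as.integer(year), persons = persons,
                 cycle_length = as.integer(cycle_length)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  live <- x$persons[x$persons$alive, , drop = FALSE]
  cat("<population_state> year", x$year, "-", nrow(live), "live persons,",
      format(sum(live$weight), big.mark = ","), "represented\n")
  invisible(x)
}

#' Total represented (live) population
#' @param state a `population_state`.
#' @return weighted count of live persons.
#' @export
live_weight <- function(state) {
  p <- state$persons
  sum(p$weight[p$alive])
}

person_columns <- function() {
  c("person_id", "age", "sex", "education", "immigrant", DISEASES,
    "smoker", "obese", "activity_limited", "cognitively_impaired",
    "in_ltc", "alive", "weight")
}

decade_band <- function(age) pmin((age - 30L) %/% 10L + 1L, 8L)

# Correlated uniforms for hypertension/heart disease through one shared
# logistic latent factor; the rank transform restores exact uniform
# marginals so prevalence targets are preserved.
latent_uniform <- function(z, loading, n) {
  s <- loading * z + stats::rlogis(n)
  (rank(s, ties.method = "first") - 0.5) / n
}

#' Generate the synthetic base population
#'
#' Draws `n` persons aged 30-110 with demographic attributes, risk factors,
#' disability flags and the seven chronic-disease flags, assigned from the
#' age-specific prevalence curves in `config`.  Hypertension and heart
#' disease co-occur through a shared logistic latent factor; all other
#' diseases are independent given age.  Survey weights are drawn uniformly
#' around equal weights and scaled to `config$represented_population`.
#' Deterministic given `(n, seed, config)`.
#'
#' @param n number of persons (>= 1).
#' @param seed integer RNG seed.
#' @param config settings from [default_config()].
#' @return a [population_state()] at `config$base_year`.
#' @export
#' @examples
#' pop <- make_base_population(500, seed = 1, config = default_config(n = 500))
#' pop
make_base_population <- function(n, seed = 1L, config = default_config(n = n)) {
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop_config("n: must be a positive count")
  n <- as.integer(n)
  validate_config(config)
  set.seed(substream(seed, 0L))

  # ages: expand 5-year band weights to single years of age
  bw <- config$demography$age_band_weights
  ages_by_band <- lapply(seq_len(N_AGE_BANDS), function(b) {
    lo <- AGE_BAND_BREAKS[b]
    lo:min(lo + 4L, MAX_AGE)
  })
  age_support <- unlist(ages_by_band)
  age_prob <- unlist(mapply(function(a, w) rep(w / length(a), length(a)),
                            ages_by_band, bw, SIMPLIFY = FALSE))
  age <- sample(age_support, n, replace = TRUE, prob = age_prob)

  sex <- ifelse(stats::runif(n) < config$demography$male, "male", "female")
  education <- sample.int(3L, n, replace = TRUE,
                          prob = config$demography$education)
  immigrant <- stats::runif(n) < config$demography$immigrant

  band10 <- decade_band(age)
  z <- stats::rlogis(n)  # shared comorbidity latent
  flags <- list()
  for (d in DISEASES) {
    targ <- config$prevalence[[d]]
    if (is.null(targ)) stop_config("prevalence$", d, ": missing")
    p <- targ[band10]
    u <- if (d %in% c("hypertension", "heart_disease"))
      latent_uniform(z, config$comorbidity_loading, n) else stats::runif(n)
    flags[[d]] <- u < p
  }

  rf <- config$risk_factors
  smoker <- stats::runif(n) < rf$smoking
  obese <- stats::runif(n) < rf$obesity
  activity_limited <- stats::runif(n) < rf$activity_limited[band10]
  cognitively_impaired <- stats::runif(n) <
    pmin(rf$cognitive_base + 0.5 * flags$dementia, 1)
  in_ltc <- stats::runif(n) < rf$in_ltc[band10]

  w0 <- stats::runif(n, 1 - config$weight_jitter, 1 + config$weight_jitter)
  weight <- w0 * config$represented_population / sum(w0)

  persons <- data.frame(person_id = seq_len(n), age = age, sex = sex,
                        education = education, immigrant = immigrant,
                        flags, smoker = smoker, obese = obese,
                        activity_limited = activity_limited,
                        cognitively_impaired = cognitively_impaired,
                        in_ltc = in_ltc, alive = TRUE, weight = weight,
                        stringsAsFactors = FALSE)
  population_state(config$base_year, persons)
}

#' Weighted disease prevalence in a population state
#' @param state a `population_state`.
#' @param disease one of the tracked disease names.
#' @return weighted prevalence among live persons.
#' @export
prevalence_of <- function(state, disease) {
  stopifnot(disease %in% DISEASES)
  p <- state$persons[state$persons$alive, , drop = FALSE]
  sum(p$weight * p[[disease]]) / sum(p$weight)
}

#' Write and read a population snapshot
#'
#' One CSV row per person with the documented header, plus a JSON metadata
#' sidecar (`<path>.meta.json`) recording year, seed and config hash.
#'
#' @param state a `population_state`.
#' @param path CSV file path.
#' @param seed,config optional provenance recorded in the sidecar.
#' @return `read_population()` returns a `population_state`.
#' @export
write_population <- function(state, path, seed = NULL, config = NULL) {
  utils::write.csv(state$persons[, person_columns()], path, row.names = FALSE)
  meta <- list(year = state$year, cycle_length = state$cycle_length,
               n = nrow(state$persons),
               seed = seed,
               config_hash = if (!is.null(config)) config_hash(config))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  persons <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop("read_population: missing metadata sidecar ", meta_path)
  meta <- jsonlite::fromJSON(meta_path)
  population_state(meta$year, persons, meta$cycle_length)
}
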
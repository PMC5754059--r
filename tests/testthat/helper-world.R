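# Shared fixtures, built in code.  The large world used by the acceptance
# suite is memoized so several test files can share one generation.

.world_cache <- new.env(parent = emptyenv())

small_world <- function(n = 2000, seed = 7) {
  key <- paste0("w", n, "_", seed)
  if (is.null(.world_cache[[key]])) {
    cfg <- default_config(n = n)
    pop <- make_base_population(n, seed = seed, config = cfg)
    truth <- make_true_parameters(1, cfg)
    .world_cache[[key]] <- list(config = cfg, pop = pop, truth = truth)
  }
  .world_cache[[key]]
}

acceptance_world <- function() small_world(n = 20000, seed = 7)

# memoized calibrations shared by the acceptance blocks
acceptance_calibration <- function(type) {
  key <- paste0("cal_", type)
  if (is.null(.world_cache[[key]])) {
    w <- acceptance_world()
    .world_cache[[key]] <- calibrate_multiplier(
      scenario_spec(type), w$pop, w$truth, seeds = 1:10, tol = 0.005)
  }
  .world_cache[[key]]
}

# a tiny deterministic person table for arithmetic-level checks
toy_persons <- function(n = 1, age = 60, sex = "female", weight = 1,
                        diseases = character()) {
  p <- data.frame(person_id = seq_len(n), age = age, sex = sex,
                  education = 2L, immigrant = FALSE,
                  diabetes = FALSE, hypertension = FALSE, stroke = FALSE,
                  cancer = FALSE, heart_disease = FALSE, lung_disease = FALSE,
                  dementia = FALSE, smoker = FALSE, obese = FALSE,
                  activity_limited = FALSE, cognitively_impaired = FALSE,
                  in_ltc = FALSE, alive = TRUE, weight = weight,
                  stringsAsFactors = FALSE)
  for (d in diseases) p[[d]] <- TRUE
  p
}

# intercept-only transition model with a given base probability
intercept_model <- function(outcome, p) {
  transition_model(outcome, character(), c(`(Intercept)` = log(-log(1 - p))))
}
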
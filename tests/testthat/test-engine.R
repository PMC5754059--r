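test_that("damped trends follow the 1, 1/2, 1/4, 0 decade rule", {
  got <- trend_value(0.20, -0.04, c(2010, 2015, 2020, 2030, 2040, 2050))
  expect_equal(got, c(0.20, 0.18, 0.16, 0.14, 0.13, 0.13))
  # proportions stay in [0, 1]
  expect_equal(trend_value(0.02, -0.04, 2050), 0)
})

test_that("entry cohorts are 30/31 with trend-adjusted composition", {
  w <- small_world(2000)
  st <- population_state(2030L, w$pop$persons)
  out <- add_entry_cohort(st, 2030, w$config, cohort_weight = 50000,
                          n_entrants = 400, seed = 6)
  ent <- out$persons[seq(nrow(st$persons) + 1, nrow(out$persons)), ]
  expect_true(all(ent$age %in% c(30L, 31L)))
  expect_equal(sum(ent$weight), 50000)
  expect_true(all(!ent$in_ltc))
  # entrant smoking reflects the damped trend at 2030 (0.20 - 0.04 - 0.02)
  expect_lt(abs(mean(ent$smoker) - 0.14), 3 * sqrt(0.14 * 0.86 / 400))
  # zero cohort leaves the state unchanged
  same <- add_entry_cohort(st, 2030, w$config, cohort_weight = 0,
                           n_entrants = 0, seed = 6)
  expect_identical(same$persons, st$persons)
  expect_error(add_entry_cohort(st, 2028, w$config, 1, 1, 1), "!=")
  expect_error(add_entry_cohort(st, 2030, w$config, NULL, 10, 1),
               "cohort-size schedule")
})

test_that("direct standardization obeys its identities", {
  # two bands, equal reference -> arithmetic mean
  expect_equal(direct_standardized_rate(c(0.02, 0.06), c(0.5, 0.5)), 0.04)
  # halving rates halves the standardized rate
  expect_equal(direct_standardized_rate(c(0.01, 0.03), c(0.5, 0.5)), 0.02)
  expect_error(direct_standardized_rate(c(0.1, 0.2), c(0.6, 0.6)), "sum to 1")
  expect_error(direct_standardized_rate(c(NA, 0.2), c(0.5, 0.5)),
               "empty age band")
  # zero-reference bands may be empty
  expect_equal(direct_standardized_rate(c(NA, 0.2), c(0, 1)), 0.2)
})

test_that("standardization with the population's own structure is the crude rate", {
  w <- small_world(2000)
  run <- run_projection(w$pop, w$truth, horizon = 2020, seed = 3,
                        compute_costs = FALSE)
  k <- match(2016L, run$years)
  collapse <- function(v) c(v[1:11], sum(v[12:16]))
  own <- collapse(run$pop_by_band[, k])
  crude <- sum(run$deaths_cvd_by_band[, k]) / sum(run$pop_by_band[, k])
  got <- age_adjusted_cvd_death_rate(run, 2016, reference = own / sum(own))
  expect_equal(unname(got), crude, tolerance = 1e-12)
})

test_that("conservation: no mortality and no entrants keeps weight constant", {
  cfg <- default_config(n = 1000)
  # ages concentrated at 40-64: nobody ages out by 2030, no 30-31 entrants
  cfg$demography$age_band_weights <- c(0, 0, 1, 1, 1, 1, 1, rep(0, 9))
  cfg$mortality_improvement <- 0
  pop <- make_base_population(1000, seed = 5, config = cfg)
  truth <- make_true_parameters(1, cfg)
  truth$transitions$models$death$scale <- 0
  run <- run_projection(pop, truth, horizon = 2030, seed = 2,
                        compute_costs = FALSE)
  expect_equal(unname(run$pop_total), rep(live_weight(pop), length(run$years)),
               tolerance = 1e-9)
  expect_equal(sum(run$deaths), 0)
})

test_that("projections are deterministic and the ledger closes", {
  w <- small_world(2000)
  a <- run_projection(w$pop, w$truth, horizon = 2050, seed = 17)
  b <- run_projection(w$pop, w$truth, horizon = 2050, seed = 17)
  expect_identical(a, b)
  expect_lt(check_ledger(a), 1e-6)
  # an independent demographic balance oracle from the output ledger
  recon <- w$pop
  implied <- live_weight(recon) + cumsum(-a$deaths - a$ageouts + a$entrants)
  expect_equal(unname(a$pop_total), unname(implied), tolerance = 1e-9)
})

test_that("2050 population lies between the stand-in growth projections", {
  w <- acceptance_world()
  run <- run_projection(w$pop, w$truth, horizon = 2050, seed = 1,
                        compute_costs = FALSE)
  bounds <- w$config$pop_2050_bounds
  expect_gt(unname(run$pop_total["2050"]), bounds[["low"]])
  expect_lt(unname(run$pop_total["2050"]), bounds[["high"]])
})

test_that("no live person ever leaves [30, 110]", {
  w <- small_world(1500)
  run <- run_projection(w$pop, w$truth, horizon = 2050, seed = 9,
                        compute_costs = FALSE)
  p <- run$final_state$persons
  expect_true(all(p$age[p$alive] >= 30 & p$age[p$alive] <= 110))
})

test_that("lowering CVD mortality never reduces expected person-years", {
  w <- small_world(1500)
  spec <- scenario_spec("mortality", multiplier = 0.6)
  py <- vapply(1:20, function(s) {
    base <- run_projection(w$pop, w$truth, horizon = 2024, seed = s,
                           compute_costs = FALSE)
    scen <- run_projection(w$pop, w$truth, spec, horizon = 2024, seed = s,
                           compute_costs = FALSE)
    sum(scen$person_years) - sum(base$person_years)
  }, numeric(1))
  expect_gt(mean(py), 0)
})

test_that("projection accessors summarize coherently", {
  w <- small_world(500)
  run <- run_projection(w$pop, w$truth, horizon = 2020, seed = 2)
  s <- summary(run)
  expect_equal(s$year, run$years)
  expect_equal(s$population, unname(run$pop_total))
  m <- projection_metrics(run)
  expect_true(all(c("year", "metric", "scenario", "value") %in% names(m)))
  expect_error(run_projection(w$pop, w$truth, horizon = 2010, seed = 1),
               "horizon")
})
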
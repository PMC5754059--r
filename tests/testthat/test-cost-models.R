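two_part_stub <- function(participation_logit, log_mean, unit_cost = 50) {
  cost_model_set(list(stub = list(
    participation = list(link = "logit", covariates = character(),
                         coef = c(`(Intercept)` = participation_logit)),
    intensity = list(covariates = character(),
                     coef = c(`(Intercept)` = log_mean)),
    unit_cost = unit_cost)))
}

test_that("expected_use is the two-part product", {
  p <- toy_persons()
  # participation probability ~0 silences any intensity
  dead_part <- two_part_stub(-30, log(50))
  expect_lt(expected_use(p, "stub", dead_part), 1e-8)
  # participation 0.5 x conditional mean 4 = 2
  half <- two_part_stub(0, log(4))
  expect_equal(expected_use(p, "stub", half), 2, tolerance = 1e-12)
  expect_error(expected_use(p, "nope", half), "unknown category")
})

test_that("refitted two-part model recovers expected use within 5%", {
  w <- acceptance_world()
  persons <- w$pop$persons
  use <- simulate_use(persons, w$truth$costs, seed = 13)
  for (cat in c("generalist_visits", "hospital_nights")) {
    covs <- w$truth$costs$categories[[cat]]$participation$covariates
    refit <- cost_model_set(stats::setNames(list(
      fit_two_part(use[[cat]], persons, covs,
                   w$truth$costs$categories[[cat]]$unit_cost)), cat))
    mu_true <- expected_use(persons, cat, w$truth$costs)
    mu_hat <- expected_use(persons, cat, refit)
    mae <- mean(abs(mu_hat - mu_true))
    expect_lt(mae / mean(mu_true), 0.05, label = cat)
  }
})

test_that("structural growth factor follows the declining schedule", {
  sched <- default_config(n = 10)$growth_schedule
  expect_equal(structural_growth_factor(2012, sched), 1)
  expect_equal(structural_growth_factor(2015, sched), 1.015^3,
               tolerance = 1e-12)
  expect_equal(structural_growth_factor(2018, sched), 1.015^6,
               tolerance = 1e-12)
  # zero growth after 2038
  expect_equal(structural_growth_factor(2045, sched),
               structural_growth_factor(2038, sched))
  expect_error(structural_growth_factor(2010, sched), "before base_year")
})

test_that("growth factors telescope: ratios depend only on in-between rates", {
  sched <- default_config(n = 10)$growth_schedule
  f <- structural_growth_factor(c(2020, 2035), sched)
  ratio <- f[2] / f[1]
  # changing the first segment's rate (2013-2018, before the window) must
  # not move the ratio over (2020, 2035]
  sched2 <- sched
  sched2$rates[1] <- 0.05
  g <- structural_growth_factor(c(2020, 2035), sched2)
  # direct product over the in-between years as the oracle
  oracle <- prod(1 + c(rep(0.010, 8), rep(0.005, 7)))
  expect_equal(ratio, oracle, tolerance = 1e-12)
  expect_equal(g[2] / g[1], ratio, tolerance = 1e-12)
})

test_that("aggregate_costs does weighted two-part arithmetic", {
  sched <- default_config(n = 10)$growth_schedule
  costs <- two_part_stub(0, log(4), unit_cost = 50)
  names(costs$categories) <- "hospital_nights"
  costs$categories$specialist_visits <- costs$categories$hospital_nights
  costs$categories$generalist_visits <- costs$categories$hospital_nights
  st <- population_state(2012L, toy_persons(weight = 100))
  out <- aggregate_costs(st, costs, sched, 2012,
                         hospital_share = c(specialist_visits = 0,
                                            generalist_visits = 0))
  # one person, weight 100, expected 2 uses, $50, factor 1 -> $10,000
  expect_equal(unname(out["hospital_nights"]), 10000)
  # empty live population
  empty <- st
  empty$persons$alive <- FALSE
  expect_equal(unname(aggregate_costs(empty, costs, sched, 2012)),
               c(0, 0, 0))
  # linear in weights
  dbl <- population_state(2012L, toy_persons(weight = 200))
  out2 <- aggregate_costs(dbl, costs, sched, 2012,
                          hospital_share = c(specialist_visits = 0,
                                             generalist_visits = 0))
  expect_equal(unname(out2), 2 * unname(out))
  expect_error(aggregate_costs(st, costs, sched, 2014), "!=")
})

test_that("hospital-setting consultation share folds into hospitalizations", {
  w <- small_world(500)
  st <- population_state(2012L, w$pop$persons)
  no_fold <- aggregate_costs(st, w$truth$costs, w$config$growth_schedule,
                             2012, c(specialist_visits = 0,
                                     generalist_visits = 0))
  fold <- aggregate_costs(st, w$truth$costs, w$config$growth_schedule,
                          2012, c(specialist_visits = 0.3,
                                  generalist_visits = 0.1))
  expect_equal(sum(fold), sum(no_fold))  # folding moves, never creates, cost
  expect_equal(unname(fold["specialist_visits"]),
               unname(0.7 * no_fold["specialist_visits"]))
  expect_equal(unname(fold["hospital_nights"]),
               unname(no_fold["hospital_nights"] +
                        0.3 * no_fold["specialist_visits"] +
                        0.1 * no_fold["generalist_visits"]))
})

test_that("normalize_index rescales to 100 at the base value", {
  s <- c(`2012` = 50, `2030` = 50, `2050` = 100)
  expect_equal(unname(normalize_index(s, 2012, 50)), c(100, 100, 200))
  # proportionality: 10% below a baseline index of 197.8
  expect_equal(unname(normalize_index(0.9 * 197.8, 2050, 100)), 178.02)
  expect_error(normalize_index(s, 2012, 0), "positive")
  expect_error(normalize_index(s, 2012, -5), "positive")
})

test_that("with equal unit costs and growth off, cost index tracks expected use", {
  w <- small_world(500)
  costs <- w$truth$costs
  for (cat in names(costs$categories)) costs$categories[[cat]]$unit_cost <- 1
  flat <- list(breaks = c(2012L), rates = c(0))
  st1 <- population_state(2012L, w$pop$persons)
  agg <- aggregate_costs(st1, costs, flat, 2012,
                         c(specialist_visits = 0, generalist_visits = 0))
  for (cat in names(costs$categories)) {
    eu <- sum(st1$persons$weight * expected_use(st1$persons, cat, costs))
    expect_equal(unname(agg[cat]), eu, tolerance = 1e-9)
  }
})
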
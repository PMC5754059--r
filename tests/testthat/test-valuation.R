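test_that("period life expectancy honours the cap and half-cycle credit", {
  q0 <- stats::setNames(rep(0, 80), 30:109)
  expect_equal(period_life_expectancy(q0, 65), 45)   # capped at age 110
  expect_equal(period_life_expectancy(q0, 30), 80)
  q1 <- q0; q1["65"] <- 1
  expect_equal(period_life_expectancy(q1, 65), 1)    # half-cycle credit
  expect_error(period_life_expectancy(q0, 111), "above")
  expect_equal(period_life_expectancy(q0, 110), 0)
})

test_that("constant-hazard life expectancy matches the geometric-series oracle", {
  q <- 0.2
  sched <- stats::setNames(rep(q, 80), 30:109)
  # independent closed form: 22 full 2-year cycles from 65 to 109, then a
  # truncated 1-year interval to the cap; survivors credit w, decedents w/2
  k <- 0:21
  full <- sum((1 - q)^k * 2 * (1 - q / 2))
  q_half <- 1 - (1 - q)^(1 / 2)
  oracle <- full + (1 - q)^22 * 1 * (1 - q_half / 2)
  expect_equal(period_life_expectancy(sched, 65), oracle, tolerance = 1e-12)
  # same closed form via the geometric sum, as a cross-check of the oracle
  expect_equal(full, 2 * (1 - q / 2) * (1 - (1 - q)^22) / q, tolerance = 1e-12)
})

test_that("present value matches geometric discounting", {
  expect_equal(present_value(c(`2012` = 250), 0.9, 2012, 2012), 250)
  flows <- c(`2013` = 100, `2014` = 100)
  expect_equal(present_value(flows, 0, 2012, 2014), 200)
  expect_equal(present_value(flows, 0.03, 2012, 2014),
               100 / 1.03 + 100 / 1.03^2)
  expect_equal(present_value(flows, 0.03, 2012, 2014), 191.3469,
               tolerance = 1e-4)
  expect_error(present_value(flows, 0.03, 2012, 2011), "horizon")
  expect_error(present_value(flows, -1, 2012, 2014), "rate")
})

test_that("discounting identity: PV grows by the discounted final-year flow", {
  set.seed(8)
  yrs <- 2012:2050
  flows <- stats::setNames(runif(length(yrs), -50, 150), yrs)
  for (H in c(2020, 2035, 2050)) {
    lhs <- present_value(flows, 0.03, 2012, H)
    rhs <- present_value(flows, 0.03, 2012, H - 1) +
      flows[as.character(H)] / 1.03^(H - 2012)
    expect_equal(lhs, unname(rhs), tolerance = 1e-10)
  }
})

test_that("late-loaded positive flows discount monotonically in the rate", {
  yrs <- 2012:2050
  late <- stats::setNames(c(rep(0, 20), seq(10, 190, by = 10)), yrs)
  pv <- vapply(c(0.01, 0.03, 0.05), function(r)
    present_value(late, r, 2012, 2050), numeric(1))
  expect_true(all(diff(pv) < 0))  # 1% > 3% > 5%
})

test_that("life-years gained accounting follows the person-years ledger", {
  mk <- function(py) list(person_years_annual = py)
  py0 <- stats::setNames(rep(1000, 5), 2012:2016)
  expect_equal(life_years_gained(mk(py0), mk(py0))$annual, rep(0, 5))
  # one person of weight 1000 surviving one extra full cycle adds 2000
  # person-years split over that cycle's two years
  py1 <- py0 + c(0, 0, 1000, 1000, 0)
  g <- life_years_gained(mk(py0), mk(py1))
  expect_equal(g$annual, c(0, 0, 1000, 1000, 0))
  expect_equal(g$cumulative, cumsum(g$annual))
  expect_equal(sum(g$annual), 2000)
  gk <- life_years_gained(mk(py0), mk(py1), units = "thousands")
  expect_equal(sum(gk$annual), 2)
  bad <- list(person_years_annual = stats::setNames(rep(0, 3), 2012:2014))
  expect_error(life_years_gained(mk(py0), bad), "mismatched")
})

test_that("value of life-years is linear and respects closed forms", {
  gains <- stats::setNames(rep(0, 10), 2012:2021)
  expect_equal(value_life_years(gains, 2e5, 0.03, 2012, 2021), 0)
  gains[] <- 5
  v1 <- value_life_years(gains, 2e5, 0.03, 2012, 2021)
  expect_equal(value_life_years(gains, 4e5, 0.03, 2012, 2021), 2 * v1)
  expect_equal(value_life_years(gains, 2e5, 0, 2012, 2021), 10 * 5 * 2e5)
  expect_error(value_life_years(gains, 0, 0.03, 2012, 2021), "vsly")
})

test_that("replication sets have the contracted shape and determinism", {
  w <- small_world(800)
  spec <- scenario_spec("mortality", multiplier = 0.8)
  rs <- run_replications(w$pop, w$truth, spec, n_param_draws = 2,
                         n_sim_seeds = 2, master_seed = 3,
                         panel_cycles = 3, horizon = 2020)
  expect_s3_class(rs, "replication_set")
  expect_length(rs$replicates, 4)  # draws x seeds
  rs2 <- run_replications(w$pop, w$truth, spec, n_param_draws = 2,
                          n_sim_seeds = 2, master_seed = 3,
                          panel_cycles = 3, horizon = 2020)
  expect_equal(rs$replicates, rs2$replicates)
  expect_error(run_replications(w$pop, w$truth, spec, 0, 1, 1), ">= 1")
  single <- run_replications(w$pop, w$truth, spec, 1, 1, master_seed = 5,
                             panel_cycles = 3, horizon = 2020)
  expect_length(single$replicates, 1)
})

test_that("valuation tables hold their identities per replicate", {
  w <- small_world(800)
  spec <- scenario_spec("mortality", multiplier = 0.8)
  rs <- run_replications(w$pop, w$truth, spec, n_param_draws = 2,
                         n_sim_seeds = 2, master_seed = 3,
                         panel_cycles = 3, horizon = 2030)
  vt <- build_valuation_table(rs, horizons = c(2020L, 2030L))
  for (h in seq_along(vt$horizons)) {
    comp <- vt$cells[, c("hospital_nights", "specialist_visits",
                         "generalist_visits"), h, drop = FALSE]
    sub <- vt$cells[, "healthcare_subtotal", h]
    tot <- vt$cells[, "total", h]
    ly <- vt$cells[, "life_years_value", h]
    expect_equal(apply(comp, 1, sum), sub, tolerance = 1e-12)
    expect_equal(sub + ly, tot, tolerance = 1e-12)
  }
  # degenerate bands: identical replicates give p5 = mean = p95
  one <- rs$replicates[1]
  vt1 <- build_valuation_table(c(one, one, one), horizons = 2030L)
  expect_equal(vt1$table$p5, vt1$table$mean, tolerance = 1e-12)
  expect_equal(vt1$table$p95, vt1$table$mean, tolerance = 1e-12)
  expect_error(build_valuation_table(list()), "empty")
})

test_that("adding parameter draws widens uncertainty bands in expectation", {
  w <- small_world(800)
  spec <- scenario_spec("mortality", multiplier = 0.8)
  spread <- function(n_draws, master) {
    rs <- run_replications(w$pop, w$truth, spec, n_param_draws = n_draws,
                           n_sim_seeds = 3, master_seed = master,
                           panel_cycles = 3, horizon = 2024)
    vt <- build_valuation_table(rs, horizons = 2024L)
    stats::var(vt$cells[, "total", 1])
  }
  sim_only <- vapply(1:3, function(m) spread(1, m), numeric(1))
  with_param <- vapply(1:3, function(m) spread(3, m), numeric(1))
  expect_gt(mean(with_param), mean(sim_only))
})
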
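test_that("transition_probability honours identity, scaling and clamping", {
  models <- transition_model_set(list(intercept_model("death", 0.4)))
  p <- toy_persons()
  expect_equal(transition_probability(p, "death", models, 1), 0.4,
               tolerance = 1e-12)
  # multipliers act on the probability scale
  expect_equal(transition_probability(p, "death", models, 0.5), 0.2,
               tolerance = 1e-12)
  expect_equal(transition_probability(p, "death", models, 10), 1)
  expect_error(transition_probability(p, "nope", models), "unknown outcome")
  expect_error(transition_probability(p, "death", models, 0), "positive")
  expect_error(transition_probability(p, "death", models, -1), "positive")
})

test_that("multiplier 1 reproduces the raw cloglog probability", {
  w <- small_world(500)
  p <- w$pop$persons[1:50, ]
  m <- w$truth$transitions$models$inc_heart_disease
  eta <- -4.95 + 0.55 * (p$age - 60) / 10 - 0.08 * ((p$age - 60) / 10)^2 +
    0.4 * (p$sex == "male") + 0.5 * p$smoker + 0.2 * p$obese +
    0.55 * p$hypertension + 0.45 * p$diabetes
  expect_equal(
    transition_probability(p, "inc_heart_disease", w$truth$transitions),
    cloglog_prob(eta), tolerance = 1e-12)
})

test_that("apply_transitions respects degenerate multipliers", {
  w <- small_world(800)
  st <- w$pop
  # no deaths, no incidence: everyone survives and ages exactly 2 years
  frozen <- apply_transitions(st, w$truth$transitions,
                              multipliers = list(
                                death_all = 0,
                                incidence = as.list(stats::setNames(
                                  rep(0, 7),
                                  c("diabetes", "hypertension", "stroke",
                                    "cancer", "heart_disease",
                                    "lung_disease", "dementia")))),
                              rng_seed = 3)
  expect_equal(frozen$year, st$year + 2L)
  expect_true(all(frozen$persons$alive))
  expect_equal(frozen$persons$age, st$persons$age + 2L)
  for (d in c("diabetes", "hypertension", "stroke", "cancer",
              "heart_disease", "lung_disease", "dementia"))
    expect_identical(frozen$persons[[d]], st$persons[[d]])
  # certain death: zero live weight afterwards
  doomed <- apply_transitions(st, w$truth$transitions,
                              multipliers = list(death_all = 1e9),
                              rng_seed = 3)
  expect_equal(live_weight(doomed), 0)
})

test_that("realized weighted event counts match the binomial oracle", {
  w <- acceptance_world()
  st <- w$pop
  p_death <- transition_probability(st$persons, "death", w$truth$transitions)
  nxt <- apply_transitions(st, w$truth$transitions, rng_seed = 12)
  died <- !nxt$persons$alive & nxt$persons$age <= 110
  wgt <- st$persons$weight
  expected <- sum(wgt * p_death)
  se <- sqrt(sum(wgt^2 * p_death * (1 - p_death)))
  expect_lt(abs(sum(wgt[died]) - expected), 3 * se)
})

test_that("raising a coefficient with positive covariate value never lowers the probability", {
  w <- small_world(500)
  persons <- w$pop$persons[1:200, ]
  for (nm in c("death", "inc_heart_disease", "inc_stroke", "ltc_admission")) {
    m <- w$truth$transitions$models[[nm]]
    base <- transition_probability(persons, nm, w$truth$transitions)
    for (cv in m$covariates) {
      bumped <- w$truth$transitions
      bumped$models[[nm]]$coef[[cv]] <- m$coef[[cv]] + 0.5
      pb <- transition_probability(persons, nm, bumped)
      x <- cvdmicrosim:::design_matrix(persons, m$covariates)[, cv]
      expect_true(all(pb[x > 0] >= base[x > 0] - 1e-12),
                  label = paste(nm, cv))
    }
  }
})

test_that("disease flags are absorbing across a multi-cycle run", {
  w <- small_world(1500)
  st <- w$pop
  prev <- st$persons
  for (k in 1:8) {
    st <- apply_transitions(st, w$truth$transitions, rng_seed = 100 + k)
    cur <- st$persons
    for (d in c("diabetes", "hypertension", "stroke", "cancer",
                "heart_disease", "lung_disease", "dementia")) {
      # align by person_id; no flag ever transitions 1 -> 0
      common <- intersect(prev$person_id, cur$person_id)
      a <- prev[[d]][match(common, prev$person_id)]
      b <- cur[[d]][match(common, cur$person_id)]
      expect_false(any(a & !b), label = paste("cycle", k, d))
    }
    prev <- cur
  }
})

test_that("missing outcome model raises a configuration error", {
  w <- small_world(300, seed = 2)
  broken <- w$truth$transitions
  broken$models$death <- NULL
  expect_error(apply_transitions(w$pop, broken, rng_seed = 1),
               "missing transition model")
})

test_that("estimation and simulation round-trip recovers generating parameters", {
  # moderate-scale version of the recovery oracle for two key outcomes;
  # the full every-outcome check runs in the acceptance suite
  w <- acceptance_world()
  panel <- simulate_panel(w$pop, w$truth, n_cycles = 4, seed = 31)
  refit <- fit_transition_models(panel, w$truth$transitions)
  for (nm in c("death", "inc_hypertension")) {
    fit <- refit$fits[[nm]]
    truth_coef <- w$truth$transitions$models[[nm]]$coef
    z <- abs(coef(fit) - truth_coef) / fit$se
    expect_true(all(z < 3), label = paste(nm, "recovery:",
                                          paste(round(z, 2), collapse = " ")))
  }
})
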
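#' Period life expectancy from a two-year mortality schedule
#'
#' Life-table expectation of remaining years at `at_age`, walking two-year
#' cycles with half-cycle credit for decedents and a hard cap at age 110
#' (a final truncated interval, if any, is credited pro rata with the
#' cycle probability rescaled on the hazard scale).
#'
#' @param mortality named numeric vector of two-year death probabilities,
#'   names are ages covering `at_age` .. 109 (values in \[0, 1\]).
#' @param at_age starting age (<= 110).
#' @return expected remaining years.
#' @export
#' @examples
#' q <- stats::setNames(rep(0, 80), 30:109)
#' period_life_expectancy(q, 65)  # 45: capped at age 110
period_life_expectancy <- function(mortality, at_age) {
  if (at_age > MAX_AGE) stop("period_life_expectancy: at_age above ", MAX_AGE)
  if (at_age == MAX_AGE) return(0)
  q <- mortality
  if (any(q < 0 | q > 1)) stop("period_life_expectancy: probabilities outside [0, 1]")
  ages <- as.integer(names(q))
  if (any(!(seq(at_age, MAX_AGE - 1L) %in% ages)) &&
      !all(seq(at_age, MAX_AGE - 2L, by = 2L) %in% ages))
    stop("period_life_expectancy: schedule must cover ages ", at_age,
         "..", MAX_AGE - 1L)
  e <- 0; S <- 1; a <- at_age
  while (a < MAX_AGE) {
    w <- min(2, MAX_AGE - a)
    qa <- unname(q[as.character(a)])
    if (w < 2) qa <- 1 - (1 - qa)^(w / 2)  # rescale hazard to interval width
    e <- e + S * w * (1 - qa / 2)          # survivors w, decedents w/2
    S <- S * (1 - qa)
    a <- a + w
  }
  e
}

#' Life-years gained by a scenario
#'
#' Annual gain = scenario person-years minus baseline person-years (same
#' years, common random numbers); cumulative gain is the running sum.
#'
#' @param baseline,scenario `cvd_projection` objects on the same year grid.
#' @param units `"person_years"` or `"thousands"`.
#' @return data frame `(year, annual, cumulative)`.
#' @export
life_years_gained <- function(baseline, scenario,
                              units = c("person_years", "thousands")) {
  units <- match.arg(units)
  yb <- names(baseline$person_years_annual)
  ys <- names(scenario$person_years_annual)
  if (!identical(yb, ys))
    stop("life_years_gained: mismatched year grids")
  gain <- scenario$person_years_annual - baseline$person_years_annual
  if (units == "thousands") gain <- gain / 1000
  data.frame(year = as.integer(yb), annual = as.numeric(gain),
             cumulative = cumsum(as.numeric(gain)))
}

#' Present value of a flow of dollars
#'
#' `sum over y = base_year..horizon of flow(y) / (1 + rate)^(y - base_year)`;
#' the base-year flow is undiscounted.  Flows outside the window are
#' ignored.
#'
#' @param flows named numeric vector (names are calendar years).
#' @param rate annual real discount rate (> -1).
#' @param base_year year to which values are discounted.
#' @param horizon last year included (`>= base_year`).
#' @return present value in the same units as `flows`.
#' @export
#' @examples
#' present_value(c(`2013` = 100, `2014` = 100), 0.03, 2012, 2014)  # 191.3469
present_value <- function(flows, rate, base_year, horizon) {
  if (rate <= -1) stop("present_value: rate must exceed -1")
  if (horizon < base_year) stop("present_value: horizon before base_year")
  yrs <- as.integer(names(flows))
  keep <- yrs >= base_year & yrs <= horizon
  sum(flows[keep] / (1 + rate)^(yrs[keep] - base_year))
}

#' Monetary value of life-years gained
#'
#' Present value of `annual gains x value per statistical life-year`.
#'
#' @param gains named numeric vector of annual person-year gains (names are
#'   years).
#' @param vsly dollars per life-year (> 0).
#' @param rate,base_year,horizon as in [present_value()].
#' @return dollars.
#' @export
value_life_years <- function(gains, vsly, rate, base_year, horizon) {
  if (vsly <= 0) stop("value_life_years: vsly must be positive")
  present_value(gains * vsly, rate, base_year, horizon)
}

# even-year series -> annual series by linear interpolation (reporting-only
# odd years), restricted to base_year..horizon
annualize_even_series <- function(values, years, base_year = 2012L,
                                  horizon = 2050L) {
  ok <- is.finite(values)
  ann <- stats::approx(years[ok], values[ok], xout = base_year:horizon,
                       rule = 2)$y
  stats::setNames(ann, base_year:horizon)
}

# per-replicate raw material for valuation: annual savings flows by
# category (baseline - scenario) and annual life-year gains
replicate_outcome <- function(base_run, scen_run, base_year = 2012L,
                              horizon = 2050L) {
  savings <- sapply(COST_CATEGORIES, function(cat)
    annualize_even_series(base_run$costs[cat, ], base_run$years, base_year,
                          horizon) -
      annualize_even_series(scen_run$costs[cat, ], scen_run$years, base_year,
                            horizon))
  gains <- life_years_gained(base_run, scen_run)
  ly <- stats::setNames(gains$annual, gains$year)
  ly <- ly[as.integer(names(ly)) >= base_year &
             as.integer(names(ly)) <= horizon]
  list(savings = t(savings), ly_gain = ly)
}

#' Run bootstrap-parameter replications of a scenario comparison
#'
#' Propagates parameter and simulation uncertainty: transition models are
#' refitted on cluster-bootstrap resamples (by person) of a synthetic
#' estimation panel (`n_param_draws` parameter sets), and each parameter
#' set is projected with `n_sim_seeds` engine seeds, baseline and scenario
#' sharing seeds (common random numbers).  Total replicates =
#' `n_param_draws * n_sim_seeds`.  A failed bootstrap refit is retried with
#' a fresh resample, with a hard cap.
#'
#' @param pop base `population_state`.
#' @param truth a `synthetic_truth` (source of the estimation panel and of
#'   the cost models, which are held fixed).
#' @param scenario a calibrated `scenario_spec`.
#' @param n_param_draws bootstrap parameter sets (>= 1).
#' @param n_sim_seeds engine seeds per parameter set (>= 1).
#' @param master_seed master seed; every stream derives from it.
#' @param panel_cycles cycles of the estimation panel.
#' @param horizon projection horizon.
#' @param max_retries retry cap per failed refit.
#' @return an object of class `replication_set`: list of replicates, each
#'   with `savings` (category x year matrix of baseline-minus-scenario
#'   dollars) and `ly_gain` (annual person-years gained).
#' @export
run_replications <- function(pop, truth, scenario, n_param_draws = 2L,
                             n_sim_seeds = 2L, master_seed = 1L,
                             panel_cycles = 4L, horizon = 2050L,
                             max_retries = 3L) {
  if (n_param_draws < 1 || n_sim_seeds < 1)
    stop("run_replications: counts must be >= 1")
  panel <- simulate_panel(pop, truth, panel_cycles,
                          seed = substream(master_seed, 101L))
  ids <- unique(panel$person_id)
  replicates <- list()
  failures <- 0L
  for (b in seq_len(n_param_draws)) {
    truth_b <- truth
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      set.seed(substream(master_seed, 1000L + 10L * b + attempt))
      boot_ids <- sample(ids, length(ids), replace = TRUE)
      take <- split(seq_along(panel$person_id), panel$person_id)
      rows <- unlist(take[as.character(boot_ids)], use.names = FALSE)
      refit <- tryCatch(
        fit_transition_models(panel[rows, , drop = FALSE],
                              truth$transitions),
        error = function(e) e)
      if (!inherits(refit, "error")) {
        truth_b$transitions <- refit$models
        break
      }
      failures <- failures + 1L
      if (attempt > max_retries)
        stop("run_replications: bootstrap refit failed ", attempt,
             " times: ", conditionMessage(refit))
    }
    for (s in seq_len(n_sim_seeds)) {
      seed_bs <- substream(master_seed, 5000L + 100L * b + s)
      base_run <- run_projection(pop, truth_b, scenario_spec("baseline"),
                                 horizon = horizon, seed = seed_bs)
      scen_run <- run_projection(pop, truth_b, scenario,
                                 horizon = horizon, seed = seed_bs)
      replicates[[length(replicates) + 1L]] <-
        replicate_outcome(base_run, scen_run, horizon = horizon)
    }
  }
  structure(list(replicates = replicates, n_param_draws = n_param_draws,
                 n_sim_seeds = n_sim_seeds, scenario = scenario,
                 master_seed = master_seed, refit_failures = failures),
            class = "replication_set")
}

#' @export
print.replication_set <- function(x, ...) {
  cat("<replication_set>", length(x$replicates), "replicates (",
      x$n_param_draws, "parameter draws x", x$n_sim_seeds, "seeds ) -",
      x$scenario$type, "scenario\n")
  invisible(x)
}

# nearest-rank percentile (sorted value at ceil(p * n))
nearest_rank <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p * length(s)))]
}

#' Build a discounted valuation table
#'
#' For each replicate and horizon, computes the present value (to 2012) of
#' the three healthcare savings components, their subtotal, the monetary
#' value of life-years gained, and the grand total; then takes the mean and
#' nearest-rank 5th/95th percentiles across replicates per cell.  The
#' subtotal and total identities hold exactly within every replicate.
#'
#' @param replicates a `replication_set` (or a list of replicate outcome
#'   lists).
#' @param rate annual real discount rate (default 0.03).
#' @param vsly dollars per life-year (default 200000).
#' @param horizons horizon years (default 2020, 2035, 2050).
#' @param base_year discounting base year.
#' @return an object of class `valuation_table`: `cells` (replicate x row x
#'   horizon array of dollars), `table` (data frame of mean/p5/p95), and
#'   the settings.
#' @export
build_valuation_table <- function(replicates, rate = 0.03, vsly = 200000,
                                  horizons = c(2020L, 2035L, 2050L),
                                  base_year = 2012L) {
  reps <- if (inherits(replicates, "replication_set")) replicates$replicates
          else replicates
  if (!length(reps)) stop("build_valuation_table: empty replicate set")
  rows <- c("hospital_nights", "specialist_visits", "generalist_visits",
            "healthcare_subtotal", "life_years_value", "total")
  cells <- array(NA_real_,
                 dim = c(length(reps), length(rows), length(horizons)),
                 dimnames = list(NULL, rows, horizons))
  for (r in seq_along(reps)) {
    rep_r <- reps[[r]]
    for (h in seq_along(horizons)) {
      H <- horizons[h]
      comp <- vapply(COST_CATEGORIES, function(cat)
        present_value(rep_r$savings[cat, ], rate, base_year, H), numeric(1))
      lyv <- value_life_years(rep_r$ly_gain, vsly, rate, base_year, H)
      cells[r, , h] <- c(comp, sum(comp), lyv, sum(comp) + lyv)
    }
  }
  tab <- do.call(rbind, lapply(seq_along(horizons), function(h)
    data.frame(horizon = horizons[h], row = rows,
               mean = apply(cells[, , h, drop = FALSE], 2, mean),
               p5 = apply(cells[, , h, drop = FALSE], 2, nearest_rank, p = 0.05),
               p95 = apply(cells[, , h, drop = FALSE], 2, nearest_rank, p = 0.95),
               row.names = NULL)))
  structure(list(cells = cells, table = tab, rate = rate, vsly = vsly,
                 horizons = horizons, base_year = base_year,
                 n_replicates = length(reps)),
            class = "valuation_table")
}

#' @export
print.valuation_table <- function(x, ...) {
  cat("<valuation_table> PV to", x$base_year, "at rate", x$rate,
      "- VSLY", format(x$vsly, big.mark = ","), "-", x$n_replicates,
      "replicates\n")
  tab <- x$table
  tab$mean <- round(tab$mean / 1e6, 2)
  tab$p5 <- round(tab$p5 / 1e6, 2)
  tab$p95 <- round(tab$p95 / 1e6, 2)
  names(tab)[3:5] <- paste0(names(tab)[3:5], "_M$")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.valuation_table <- function(x, ...) x$table
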
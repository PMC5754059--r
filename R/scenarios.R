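#' Scenario specification
#'
#' Defines how a projection deviates from the baseline in pursuit of the
#' WHO-style target: a 25\% reduction in the age-adjusted death rate of
#' persons with cardiovascular disease between 2012 and 2024.
#'
#' * `baseline` - multiplier 1, no affected outcomes.
#' * `mortality` ("treatment") - multiplies the all-cause death probability
#'   of persons with lagged heart disease or stroke; ramped linearly on
#'   the reduction scale over 2012-2024.
#' * `incidence` ("prevention") - multiplies the incidence of heart
#'   disease, stroke and hypertension; ramped over 2012-2022.  Mortality
#'   coefficients are never touched.
#' * `mixed` - both channels, with `share` of the reduction delivered
#'   through incidence.
#'
#' @param type scenario type.
#' @param share fraction of the reduction achieved via incidence (mixed
#'   only).
#' @param multiplier final (fully ramped) multiplier for the single-channel
#'   scenarios.
#' @param incidence_multiplier,mortality_multiplier final multipliers for
#'   the two channels of a mixed scenario.
#' @param target_reduction target fractional reduction (default 0.25).
#' @param target_window years between which the reduction is measured.
#' @param ramp_mortality,ramp_incidence ramp windows for each channel.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(type = c("baseline", "mortality", "incidence",
                                   "mixed"),
                          share = NULL, multiplier = 1,
                          incidence_multiplier = NULL,
                          mortality_multiplier = NULL,
                          target_reduction = 0.25,
                          target_window = c(2012L, 2024L),
                          ramp_mortality = c(2012L, 2024L),
                          ramp_incidence = c(2012L, 2022L)) {
  type <- match.arg(type)
  if (type == "mixed") {
    if (is.null(share) || share < 0 || share > 1)
      stop("scenario_spec: mixed scenario needs share in [0, 1]")
    incidence_multiplier <- incidence_multiplier %||% 1
    mortality_multiplier <- mortality_multiplier %||% 1
  }
  if (multiplier <= 0 || multiplier > 1)
    stop("scenario_spec: multiplier must be in (0, 1]")
  affected <- switch(type,
    baseline = character(),
    mortality = paste0("death[", paste(CVD_MORTALITY_DISEASES, collapse = "|"),
                       "]"),
    incidence = paste0("inc_", CVD_INCIDENCE_DISEASES),
    mixed = c(paste0("death[", paste(CVD_MORTALITY_DISEASES, collapse = "|"),
                     "]"), paste0("inc_", CVD_INCIDENCE_DISEASES)))
  structure(list(type = type, share = share, multiplier = multiplier,
                 incidence_multiplier = incidence_multiplier,
                 mortality_multiplier = mortality_multiplier,
                 target_reduction = target_reduction,
                 target_window = as.integer(target_window),
                 ramp_mortality = as.integer(ramp_mortality),
                 ramp_incidence = as.integer(ramp_incidence),
                 affected_outcomes = affected),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$type)
  if (x$type %in% c("mortality", "incidence"))
    cat(" (final multiplier ", format(x$multiplier, digits = 4), ")", sep = "")
  if (x$type == "mixed")
    cat(" (share ", x$share, "; incidence ",
        format(x$incidence_multiplier, digits = 4), ", mortality ",
        format(x$mortality_multiplier, digits = 4), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Ramped per-cycle multiplier
#'
#' Interpolates linearly on the reduction scale from 1 at the ramp start to
#' the final multiplier at the ramp end, holding the final value
#' afterwards; years before the ramp return 1.
#'
#' @param spec a `scenario_spec` (or a final multiplier when `window` is
#'   given directly).
#' @param year evaluation year.
#' @param channel `"mortality"` or `"incidence"` (needed for mixed specs).
#' @return the per-cycle multiplier at `year`.
#' @export
ramp_multiplier <- function(spec, year, channel = NULL) {
  if (spec$type == "baseline") return(1)
  channel <- channel %||% spec$type
  final <- switch(channel,
    mortality = if (spec$type == "mixed") spec$mortality_multiplier
                else spec$multiplier,
    incidence = if (spec$type == "mixed") spec$incidence_multiplier
                else spec$multiplier)
  window <- if (channel == "mortality") spec$ramp_mortality
            else spec$ramp_incidence
  frac <- clamp((year - window[1]) / (window[2] - window[1]), 0, 1)
  1 - frac * (1 - final)
}

# Multiplier list consumed by the engine for the cycle ending at `year`.
scenario_multipliers <- function(spec, year) {
  out <- list()
  if (spec$type %in% c("mortality", "mixed"))
    out$death_cvd <- ramp_multiplier(spec, year, "mortality")
  if (spec$type %in% c("incidence", "mixed")) {
    m <- ramp_multiplier(spec, year, "incidence")
    out$incidence <- stats::setNames(
      as.list(rep(m, length(CVD_INCIDENCE_DISEASES))),
      CVD_INCIDENCE_DISEASES)
  }
  out
}

#' Multiplicative compounding of two reductions
#'
#' Combined fractional reduction from applying two independent fractional
#' reductions: `1 - (1 - a)(1 - b)`.  Used to relate a baseline secular
#' decline and an additional scenario-induced decline.
#'
#' @param a,b fractional reductions.
#' @return the compounded reduction.
#' @export
compound_reduction <- function(a, b) 1 - (1 - a) * (1 - b)

# mean achieved reduction over seeds for a spec (common random numbers:
# the same seeds are used for every multiplier evaluated)
mean_reduction <- function(spec, base, truth, seeds, window) {
  mean(vapply(seeds, function(s) {
    out <- run_projection(base, truth, spec, horizon = window[2], seed = s,
                          compute_costs = FALSE)
    cvd_rate_reduction(out, window)
  }, numeric(1)))
}

#' Calibrate a scenario multiplier by bisection
#'
#' Finds the final multiplier in \[0, 1\] such that the mean (over seeds)
#' achieved reduction in the age-adjusted CVD death rate between the target
#' window's endpoints, measured against each run's own starting rate,
#' equals the target within `tol`.  The same seeds are used at every
#' multiplier (common random numbers), making the objective deterministic
#' and effectively monotone, so bisection converges; non-convergence after
#' `max_iter` iterations is flagged, and a target unattainable even at
#' multiplier 0 yields an explicit infeasibility result.
#'
#' @param spec a `scenario_spec` of type `mortality` or `incidence`.
#' @param base the base `population_state`.
#' @param truth a `synthetic_truth`.
#' @param seeds integer seeds averaged over.
#' @param tol tolerance on the reduction scale (default 0.005 = 0.5 pp).
#' @param max_iter maximum bisection iterations.
#' @return an object of class `calibration_result`: `multiplier`,
#'   `achieved_reduction`, `baseline_reduction`, `additional_reduction`
#'   (the scenario-induced reduction that compounds with the baseline
#'   decline), `iterations`, `history`, `converged`, `infeasible`.
#' @export
calibrate_multiplier <- function(spec, base, truth, seeds = 1:10,
                                 tol = 0.005, max_iter = 40L) {
  stopifnot(inherits(spec, "scenario_spec"),
            spec$type %in% c("mortality", "incidence"))
  target <- spec$target_reduction
  if (target <= 0 || target >= 1)
    stop("calibrate_multiplier: target_reduction must be in (0, 1)")
  window <- spec$target_window
  hist_m <- numeric(); hist_a <- numeric()
  eval_m <- function(m) {
    s <- spec; s$multiplier <- max(m, 1e-12)
    a <- mean_reduction(s, base, truth, seeds, window)
    hist_m <<- c(hist_m, m); hist_a <<- c(hist_a, a)
    a
  }
  result <- function(m, a, iters, converged, infeasible = FALSE) {
    structure(list(multiplier = m, achieved_reduction = a,
                   baseline_reduction = base_red,
                   additional_reduction = 1 - (1 - a) / (1 - base_red),
                   target_reduction = target, iterations = iters,
                   history = data.frame(multiplier = hist_m,
                                        achieved = hist_a),
                   converged = converged, infeasible = infeasible,
                   seeds = seeds, tol = tol, type = spec$type),
              class = "calibration_result")
  }
  base_red <- eval_m(1)
  if (abs(base_red - target) <= tol || base_red > target)
    return(result(1, base_red, 1L, TRUE))
  red0 <- eval_m(0)
  if (red0 < target - tol)
    return(result(0, red0, 2L, FALSE, infeasible = TRUE))
  lo <- 0; hi <- 1  # reduction is (weakly) decreasing in the multiplier
  iters <- 2L
  while (iters < max_iter) {
    iters <- iters + 1L
    mid <- (lo + hi) / 2
    a <- eval_m(mid)
    if (abs(a - target) <= tol) return(result(mid, a, iters, TRUE))
    if (a > target) lo <- mid else hi <- mid
  }
  result((lo + hi) / 2, hist_a[length(hist_a)], iters, FALSE)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>", x$type, "scenario\n")
  cat("  multiplier", format(x$multiplier, digits = 4),
      "-> achieved reduction", sprintf("%.1f%%", 100 * x$achieved_reduction),
      "(target", sprintf("%.1f%%;", 100 * x$target_reduction),
      "baseline decline", sprintf("%.1f%%)", 100 * x$baseline_reduction), "\n")
  cat("  additional reduction beyond baseline:",
      sprintf("%.1f%%", 100 * x$additional_reduction), "-",
      x$iterations, "objective evaluations;",
      if (x$infeasible) "INFEASIBLE" else if (x$converged) "converged"
      else "NOT converged", "\n")
  invisible(x)
}

#' Calibrate a mixed prevention/treatment scenario
#'
#' Splits the target between the incidence ("prevention") and mortality
#' ("treatment") channels: the incidence channel is calibrated alone to
#' deliver `share` of the gap between the baseline decline and the target,
#' then the mortality channel is calibrated, with the incidence multiplier
#' held fixed, so the combined run meets the full target.  Shares 0 and 1
#' reproduce the pure mortality and incidence scenarios exactly.
#'
#' @param share fraction of the reduction via incidence, in \[0, 1\].
#' @param base,truth,seeds,tol,max_iter as in [calibrate_multiplier()].
#' @param target_reduction target fractional reduction.
#' @return list with `spec` (a calibrated `scenario_spec`) and `result`
#'   (the `calibration_result` of the final joint check), plus
#'   `incidence_result`/`mortality_result` where applicable.
#' @export
mixed_scenario <- function(share, base, truth, seeds = 1:10, tol = 0.005,
                           max_iter = 40L, target_reduction = 0.25) {
  if (share < 0 || share > 1) stop("mixed_scenario: share must be in [0, 1]")
  if (share == 0) {
    res <- calibrate_multiplier(
      scenario_spec("mortality", target_reduction = target_reduction),
      base, truth, seeds, tol, max_iter)
    spec <- scenario_spec("mixed", share = 0, incidence_multiplier = 1,
                          mortality_multiplier = res$multiplier,
                          target_reduction = target_reduction)
    return(list(spec = spec, result = res, mortality_result = res))
  }
  if (share == 1) {
    res <- calibrate_multiplier(
      scenario_spec("incidence", target_reduction = target_reduction),
      base, truth, seeds, tol, max_iter)
    spec <- scenario_spec("mixed", share = 1,
                          incidence_multiplier = res$multiplier,
                          mortality_multiplier = 1,
                          target_reduction = target_reduction)
    return(list(spec = spec, result = res, incidence_result = res))
  }
  base_red <- mean_reduction(scenario_spec("baseline"), base, truth, seeds,
                             c(2012L, 2024L))
  inc_target <- base_red + share * (target_reduction - base_red)
  inc_res <- calibrate_multiplier(
    scenario_spec("incidence", target_reduction = inc_target),
    base, truth, seeds, tol, max_iter)
  # mortality channel picks up the remainder with incidence held fixed
  eval_joint <- function(m_mort) {
    spec <- scenario_spec("mixed", share = share,
                          incidence_multiplier = inc_res$multiplier,
                          mortality_multiplier = max(m_mort, 1e-12),
                          target_reduction = target_reduction)
    mean_reduction(spec, base, truth, seeds, c(2012L, 2024L))
  }
  lo <- 0; hi <- 1; iters <- 0L; converged <- FALSE; infeasible <- FALSE
  a_hi <- eval_joint(1)
  hist_m <- 1; hist_a <- a_hi
  m_fin <- 1; a_fin <- a_hi
  if (abs(a_hi - target_reduction) <= tol || a_hi > target_reduction) {
    converged <- TRUE
  } else {
    a_lo <- eval_joint(0)
    hist_m <- c(hist_m, 0); hist_a <- c(hist_a, a_lo)
    if (a_lo < target_reduction - tol) {
      infeasible <- TRUE; m_fin <- 0; a_fin <- a_lo
    } else {
      while (iters < max_iter) {
        iters <- iters + 1L
        mid <- (lo + hi) / 2
        a <- eval_joint(mid)
        hist_m <- c(hist_m, mid); hist_a <- c(hist_a, a)
        m_fin <- mid; a_fin <- a
        if (abs(a - target_reduction) <= tol) { converged <- TRUE; break }
        if (a > target_reduction) lo <- mid else hi <- mid
      }
    }
  }
  spec <- scenario_spec("mixed", share = share,
                        incidence_multiplier = inc_res$multiplier,
                        mortality_multiplier = m_fin,
                        target_reduction = target_reduction)
  res <- structure(list(multiplier = m_fin, achieved_reduction = a_fin,
                        baseline_reduction = base_red,
                        additional_reduction =
                          1 - (1 - a_fin) / (1 - base_red),
                        target_reduction = target_reduction,
                        iterations = iters,
                        history = data.frame(multiplier = hist_m,
                                             achieved = hist_a),
                        converged = converged, infeasible = infeasible,
                        seeds = seeds, tol = tol, type = "mixed"),
                   class = "calibration_result")
  list(spec = spec, result = res, incidence_result = inc_res)
}
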
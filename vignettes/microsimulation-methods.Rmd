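---
title: "Methods: the microsimulation model, its synthetic world, and its numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the microsimulation model, its synthetic world, and its numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdmicrosim)
```

## The model

`cvdmicrosim` is a discrete-time dynamic microsimulation on two-year
cycles.  A population of weighted persons aged 30 and over evolves from a
2010 base year to 2050.  Within each cycle, every live person faces a set
of jointly evaluated transitions — death, incidence of each of seven
chronic diseases, long-term-care admission, smoking start and quit — whose
probabilities come from discrete-time hazard models with the
complementary log-log link,

$$p = 1 - \exp(-\exp(x\beta)),$$

the discrete-time counterpart of a proportional-hazards model:
$\exp(x\beta)$ is the hazard integrated over one cycle, so covariate
effects are log-hazard-ratios.  Every covariate is a *lagged*
(start-of-cycle) state or a fixed transform of one (age enters as linear
plus quadratic terms in `(age − 60)/10` by default), which makes the
within-cycle dependency graph acyclic by construction: a disease incident
in a cycle can influence other outcomes only from the next cycle onward.
Disease flags are absorbing.  If a person draws death and an incident
disease in the same cycle, death pre-empts the *recording* of the incident
event, but the incident draw still uses lagged covariates — a fixed,
testable convention.

Each cycle the population loses decedents and persons crossing the
maximum age of 110, and gains an entry cohort at ages 30–31.  Entrant
smoking, obesity and education reflect secular decade trends damped by
decade: the full per-decade change for 2010–2020, half for 2020–2030, a
quarter for 2030–2040 and zero afterwards.  A demographic ledger — live
weight out equals live weight in minus deaths and age-outs plus
entrants — is asserted every cycle at a relative tolerance of $10^{-6}$.

## Scenarios and calibration

The scenario target is a 25% reduction, between 2012 and 2024, in the
age-standardized death rate of people with cardiovascular disease: the
weighted deaths of persons with a lagged diagnosis of heart disease or
stroke, per unit of *total* population, directly standardized over age
bands.  Two single-channel scenarios reach it:

* **mortality ("treatment")**: multiply the all-cause death probability of
  persons with lagged heart disease or stroke by $m < 1$, ramped linearly
  on the reduction scale over 2012–2024;
* **incidence ("prevention")**: multiply the incidence of heart disease,
  stroke and hypertension by $m < 1$, ramped over 2012–2022, leaving the
  death model of prevalent cases untouched.

Mixed scenarios calibrate the incidence channel to a share of the gap
between the baseline's own decline and the target, then calibrate the
mortality channel, holding incidence fixed, so the joint run meets the
full target; shares 0 and 1 collapse exactly to the pure scenarios.

Three design choices deserve flagging:

* **Multipliers act on the probability scale**, clamped to $[0,1]$, not on
  the linear predictor.  The target is a rate-scale statement ("decrease
  the death rates by 25%"), so calibration on the same scale keeps the
  instrument and the objective commensurable.  For the small per-cycle
  probabilities involved, a probability-scale multiplier is
  near-identical to a hazard multiplier.  Whether such reductions should
  scale per-cycle probabilities or annualized rates is genuinely open;
  the per-cycle probability scale is this package's documented
  convention.
* **The reduction is measured against each run's own 2012 rate**, not
  against the baseline scenario's 2024 rate: the target is "a total
  decrease of 25% between 2012 and 2024".  Since the scenario ramps start
  at 2012, the 2012 rate is common to baseline and scenario under shared
  seeds.
* **Calibration uses common random numbers**: the same seed list is used
  at every multiplier evaluated, making the bisection objective a
  deterministic, effectively monotone function of the multiplier at
  desk-scale population sizes.  Bisection stops when the achieved
  reduction is within 0.5 percentage points of target (tolerance chosen
  by us; none is stated for the quantity) or flags non-convergence after
  40 iterations; a target unattainable even at multiplier 0 returns an
  explicit infeasibility result rather than a boundary estimate.

The mortality ramp runs over the full target window 2012–2024 (only the
endpoint is specified for that channel); the incidence ramp over
2012–2022 is as specified.

## Age standardization

The reference age distribution is the projection's own 2012 population in
5-year bands, with one open-ended 85+ band.  Neither the band scheme nor
the standard population is canonical for this quantity; 5-year bands on
the 2012 base are the package's documented assumption, and collapsing
85+ keeps the standard defined when sparse very-old bands empty out at
moderate simulation sizes (an empty band with positive reference weight is
otherwise a hard error naming the band).

## The synthetic world

All estimation inputs of the original setting are confidential survey and
administrative microdata.  The package therefore *states* a synthetic
world and generates everything from it: a base population
(`make_base_population()`), "true" transition and cost parameters
(`make_true_parameters()`), and a biennial longitudinal estimation panel
(`simulate_panel()`).  The defaults were chosen once, as follows, and are
not tuned to any downstream test:

* **Demography**: 5-year age-band weights describing an aged Western
  population (about 20% of adults 30+ are 65+), 49% male, education
  shares 18/35/47%, 13% immigrants, 5 million represented persons.
* **Disease prevalence** is stepwise by 10-year band.  Curves were set so
  the weighted adult prevalence sits near published Canadian levels circa
  2010–2012: hypertension ≈ 29%, heart disease ≈ 7.5%, diabetes ≈ 9%,
  stroke ≈ 2.3%.  Hypertension and heart disease co-occur through one
  shared logistic latent factor (rank-transformed back to exact uniform
  marginals so prevalence targets are preserved); all other diseases are
  independent given age.  The joint distribution of the real data is
  unknown; the latent-factor device is a stand-in, not an estimate.
* **Mortality** is Gompertz-like on the cloglog scale (log-hazard slope
  0.087 per year of age), with the intercept set so period life
  expectancy at 65 lands near 20.5 years — and measured at 20.8 on the
  default world.  Prevalent diseases carry moderate all-cause
  log-hazard-ratios (heart disease 0.50, stroke 0.60, dementia 0.60,
  ...), i.e. hazard ratios of 1.5–2.  Early drafts used HRs above 2.5;
  with independently assigned multimorbidity at ages 90+, such hazards
  produced a large first-cycle mortality transient (the cross-section
  contained frail combinations that the dynamics would never keep alive),
  which is both unrealistic — observed all-cause HRs attenuate with age —
  and distorting for any rate measured from the first cycle.
* **Incidence** intercepts and age slopes are Taylor-matched to the
  prevalence curves: since prevalence is roughly cumulative incidence net
  of differential mortality, the log-incidence age gradient must be close
  to the log-prevalence gradient (steep before 60, attenuating after —
  hence a negative quadratic age term in every incidence model).  This
  internal consistency makes within-band prevalence drift mildly upward
  over the projection (a composition effect from higher-prevalence young
  cohorts), rather than exploding or collapsing.
* **Exogenous mortality improvement** defaults to 2.1% per year on the
  hazard scale, applied from 2012.  This is the one stated-world constant
  calibrated against an emergent quantity, as the design prescribes: it
  is set so the *baseline* scenario produces a double-digit expected
  decline in the age-standardized CVD death rate over 2012–2024
  (measured at ~11–13% across seeds), mirroring the secular decline such
  models exhibit.  Scenario calibration then supplies the rest of the
  25%, so the calibrated "additional" reductions (≈ 15–20% mortality,
  ≈ 40–50% incidence) are commensurate with the compounding arithmetic
  $1-(1-0.127)(1-0.16) \approx 0.267 \ge 0.25$.
* **Costs**: unit costs of C$55 per generalist visit, C$78 per specialist
  visit and C$1,100 per hospital night (2012 dollars, plausible for a
  single-payer system circa 2012); two-part coefficients giving roughly
  80%/55%/8% annual participation and conditional means of about 3.5/2.8/7
  for the three categories, all raised by chronic conditions, CVD most
  strongly for hospital nights.  The share of physician consultation cost
  arising in a hospital setting — folded into the hospitalization
  category — defaults to 30% for specialists and 10% for generalists (no
  number is given for this accounting; a single configurable fraction per
  category is the package's choice).
* **Entry cohorts** default to a constant total weight equal to the base
  population's 30–31-year-old weight, a stand-in for official projection
  alignment, with stand-in low/high-growth 2050 bounds (4.8M, 8.0M)
  bracketing the resulting demography.  Secular trends default to −4
  pp/decade smoking, +3 pp/decade obesity, +4 pp/decade post-secondary
  education.

What the generator does *not* emulate: survey sampling designs, strata and
non-response weighting; cause-of-death attribution; drug spending;
long-term-care facility costs beyond an admission flag; any population
under 30; and the real joint distribution of risk factors and diseases.  A
green test against this world establishes that the machinery — estimation,
projection, calibration, valuation — is internally correct at realistic
scales, not that the numbers reproduce any published magnitude estimated
on confidential data.

## Estimation

`fit_cloglog()` maximizes the Bernoulli likelihood under the cloglog link
by Fisher scoring with step-halving, declaring convergence when the
relative log-likelihood change falls below $10^{-8}$ or the gradient
max-norm below $10^{-6}$.  All-event or no-event outcomes and
(quasi-)complete separation are estimation errors with diagnostic
messages, never silently returned fits.  The independent cross-check in
the test suite is `stats::glm(family = binomial("cloglog"))`; the two
routes agree to $10^{-5}$ on simulated data.  Two-part cost models are
estimated with standard GLMs: logistic participation, and a log-linear
positive-part mean fitted by Poisson quasi-likelihood on the positive
counts, which is consistent for the conditional mean regardless of the
count distribution.

Parameter uncertainty propagates by cluster bootstrap: persons (not
person-cycles) are resampled from the estimation panel, all transition
models are refitted per draw, and each parameter set is projected under
several engine seeds, baseline and scenario sharing seeds.  Replicate
counts are configurable downward for tests; the default
headline configuration in the literature this emulates is 100 parameter
draws × 50 seeds.

## Accounting and valuation conventions

* Each cycle contributes two person-years per survivor (and per age-110
  exit) and one per within-cycle decedent (half-cycle credit).  The same
  convention gives `period_life_expectancy()` its half-cycle credit and
  its hard cap at age 110, with a pro-rata final interval when the cap
  falls mid-cycle.
* Cycle outputs are annualized by even split (person-years) or linear
  interpolation (costs at odd years); odd-year values are reporting-only.
* Flows are end-of-year; the 2012 base-year flow is undiscounted; the
  default real discount rate is 3% (1% and 5% as sensitivities), and
  life-years are valued at C$200,000.  Savings are signed
  baseline-minus-scenario, so a scenario that *raises* costs shows
  negative healthcare savings.
* Percentile bands use the nearest-rank method on the replicate
  distribution (the quantile estimator is unstated in the emulated
  setting; nearest-rank is the package's choice).  The
  subtotal-and-total identities of the valuation table hold exactly per
  replicate, before any aggregation.
* Cost indices are normalized to 100 at the *baseline scenario's* 2012
  value so scenario indices are directly comparable.
* The declining structural growth schedule applies to all three cost
  categories.  The setting this emulates states the schedule for
  hospital costs; whether physician costs received it too is not stated,
  and applying it uniformly keeps cross-category indices comparable.

## Numerical choices

* Linear predictors are clamped to $[-30, 30]$ before exponentiation;
  `cloglog_prob(-30) < 10^{-12}$, so the clamp is inert in any realistic
  configuration.
* Scenario multipliers multiply probabilities and are clamped to
  $[0, 1]$.
* Every operation draws from a single explicitly seeded stream;
  sub-streams derive from the master seed by fixed integer offsets
  (`substream()`), so replication counts never perturb unrelated draws
  and identical (seed, config) pairs are bit-for-bit reproducible.
  Within a cycle, the draw order is fixed (death, incidences in a fixed
  disease order, long-term care, smoking start, smoking quit) and every
  draw covers all persons alive at cycle start, which keeps common
  random numbers aligned across scenarios.
* Bisection brackets $[0, 1]$; with common random numbers the objective
  is deterministic, and the finite-population step size of the objective
  (a handful of weighted deaths) is well inside the 0.5 pp tolerance at
  the default scale of 20,000 persons × 10 seeds.

## Known limitations

Single-region, closed to migration except the stylized entry cohorts; no
under-30 dynamics; risk factors beyond smoking are static after the base
year; obesity affects incidence but has no direct mortality term;
calibration at small population sizes (≲ 5,000 persons) can fail to meet
the 0.5 pp tolerance because Monte Carlo noise exceeds it — the result is
then flagged unconverged rather than silently accepted.  Benefits
accruing beyond 2050 are excluded, making valuation totals lower bounds
in any world where gains persist.
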
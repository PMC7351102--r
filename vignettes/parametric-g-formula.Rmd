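---
title: "The parametric g-formula in gcomp: models, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The parametric g-formula in gcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcomp)
```

## The estimand and the estimator

`gcomp` estimates the marginal outcome distribution that would have been
observed had a study population followed a *sustained treatment strategy*:
a rule assigning treatment at every follow-up time, possibly as a function
of evolving covariates ("dynamic") or of the *natural value of treatment* —
the value treatment would have taken at `k` had the intervention been
discontinued just before `k` (the basis of threshold rules). Identification
requires the usual untestable conditions: sequential exchangeability given
the measured covariate history, positivity, and consistency. Under them the
counterfactual risk (or end-of-follow-up mean) equals the g-formula, a sum
over covariate histories of the conditional outcome distribution weighted
by the conditional covariate distributions, with treatment fixed by the
strategy.

The parametric g-formula plugs parametric models into that sum and
approximates it by Monte Carlo:

1. **Fit** (a) one conditional model per time-varying covariate, in a
   user-chosen factorisation order — the model for the j-th covariate at
   time `k` may depend on current-time values of earlier-order covariates
   and on history functions of all covariates; (b) a pooled-over-time
   logistic model for the discrete-time hazard of the outcome (survival),
   or a single cross-sectional model at the final time `K`
   (end-of-follow-up outcomes); (c) optionally a pooled logistic model for
   the competing-event hazard.
2. **Simulate** `s` covariate histories per strategy: baselines are drawn
   from the observed baseline rows (each used exactly once when `s = n`,
   resampled with replacement otherwise); at each `k >= 1` the covariates
   are drawn one at a time in factorisation order; every treatment's
   natural value is drawn from its fitted model and then replaced by the
   value the strategy assigns at that time. Risks are accumulated from the
   predicted hazards along each history,
   `R(k) = sum_{t<=k} p_t prod_{j<t}(1 - p_j)`, with the competing-event
   factors `(1 - q_t)` included when a competing event is modelled
   (competing event resolved before the outcome within each interval,
   matching the input convention that the outcome is missing on a
   competing-event row). Computing risks from hazards rather than from
   simulated event indicators leaves the estimand unchanged and reduces
   Monte Carlo variance.

Contrasts (ratios and differences) are taken against a reference strategy,
by default the natural course, which is always simulated as intervention 0.

## Input data model

One row per subject per follow-up interval, time index starting at 0 (or at
`-i` when `i` pre-baseline rows are supplied) and increasing by 1. A
subject with the event of interest in interval `k+1` has exactly `k+1` rows
with `Y = 1` on the last; censoring is encoded implicitly by record
termination without an event (the final outcome may be coded `0` or
missing — model fitting uses rows as given, so a `0` contributes to the
hazard fit and a missing value does not). A modelled competing event sets
`D = 1` on the subject's (last) row with the outcome missing.
End-of-follow-up outcomes are read from the row with `k = K` only, and
death must then be handled as censoring. `validate_gf_data()` checks all of
these rules and reports every violation rather than stopping at the first.

Pre-baseline rows participate only in history construction: lags may read
negative-time values, while cumulative averages deliberately start at
`k = 0`. The treatment of pre-baseline rows in cumulative averages is a
genuine design choice — we chose the reading that keeps `cumavg` a
function of follow-up information only, and document it rather than guess
at alternatives.

## Covariate families

Eight families are available (`gf_cov_spec()`): binary (logistic), normal
(linear, residual-SD noise), categorical (multinomial logistic via `nnet`,
reference level = first observed level in sort order), bounded normal
(standardised to `[0, 1]` by the observed range before the linear fit),
zero-inflated normal (logistic model for a nonzero value times a linear
model fitted on the nonzero rows, both sharing the covariate formula's
right-hand side; the linear part is fitted on the natural scale),
truncated normal (one-sided truncation point and direction supplied by the
user; simulation draws by inverse-CDF from the truncated distribution),
absorbing (logistic fitted on rows whose previous value is 0; a simulated
1 persists forever), and categorical time (a deterministic recoding of the
time index into user-supplied intervals, usable as a predictor; no
stochastic model — the minimal deterministic reading of that family).

Numerical choices worth knowing:

* Simulated normal-family values falling outside the range observed in the
  fitting data are **clamped to the range bounds**. This prevents runaway
  extrapolation over many simulated intervals; it is on by default and is
  the package's documented behaviour rather than an option, because every
  shipped validation exercises it. With ~10^4 fitting rows the clamping
  affects only the extreme tails and its bias is far below sampling error
  (the parameter-recovery tests bound it empirically).
* A covariate constant in its fitting rows is simulated as that constant.
* Lag padding is 0 for every family, including categorical covariates — a
  categorical covariate without a natural `"0"` level triggers a warning,
  since early rows then carry a padding level of their own.
* Degenerate responses (no variation), singular designs and non-converged
  logistic fits are errors naming the model, not silent results.

## History functions

Three pre-coded functions of history generate columns with a fixed naming
scheme that is part of the formula vocabulary: `lag{i}_Z`, `cumavg_Z` and
`lag_cumavg{i}_Z`. The maximum lag per covariate is inferred from the
model formulas rather than supplied separately. During simulation the same
features are built incrementally (running sums and lag buffers), and the
equivalence of the incremental and batch computations is property-tested.
Formulas are ordinary R model formulas, so polynomial terms and spline
bases (e.g. `splines::ns(lag1_L2, knots = ...)`) work unchanged.

## Interventions and random-number alignment

Strategies are lists of per-treatment rules with applicable times
(defaulting to all follow-up times): `static(values)`, `threshold(min,
max)`, `natural()`, or a custom function `f(k, natural_value, history)`
(which must be pure; this covers dynamic and random rules). Within every
time step the natural value of each treatment is **always drawn first**,
consuming the random-number stream even under static rules, and each
strategy's simulation restarts from the same derived seed. Consequently
seed-matched runs are aligned draw for draw: `threshold(-Inf, Inf)`
reproduces the natural course bit for bit, which the test suite asserts.
This operational definition of the natural value is a deliberate choice;
an implementation that skips the draw under static rules would give the
same estimand but lose exact seed-matched comparability.

Histories are simulated vectorised across all `s` subjects from a single R
RNG stream per strategy (not per-history substreams); reproducibility
comes from the master seed, and bootstrap replicates are seeded
individually so that results are invariant to the number of bootstrap
workers.

## Diagnostics and inference

Nonparametric natural-course benchmarks are computed from the observed
data: a discrete-time product-limit risk (Aalen-Johansen form when a
competing event is modelled; censored subjects simply leave the risk set —
no censoring weights, an interpretation documented rather than hidden),
per-time covariate means among subjects still under follow-up, and the
end-of-follow-up outcome mean among uncensored subjects. `plot()` overlays
them on the parametric natural-course estimates; close agreement supports,
but does not guarantee, absence of gross misspecification. On a saturated
fixture (one binary covariate, `K = 1`, cell-indicator formulas) the
parametric and nonparametric estimates agree to Monte Carlo error by
construction — the test suite reproduces exactly this diagnostic logic.

Inference is by nonparametric bootstrap: whole subjects are resampled with
replacement (preserving within-subject dependence), every model is
refitted and the full simulation rerun per replicate. Standard errors are
replicate standard deviations; intervals are **percentile** intervals
(2.5th/97.5th), chosen because reported intervals of this estimator are
asymmetric about the point estimate, which a normal approximation cannot
produce. Replicates whose model fitting fails are excluded and counted.
BCa/studentised intervals and analytic variances are out of scope.

## The synthetic data bed

`gf_dgp()` ships five structural processes with treatment-confounder
feedback (binary/continuous/zero-inflated/categorical covariates; survival
with and without competing events; binary and continuous end-of-follow-up
outcomes). Coefficients were fixed once so that event risks lie in the
0.2-0.7 range, giving well-separated contrasts; default sizes mirror a
realistic cohort (`n = 2500`, `K = 6`, i.e. up to 17,500 person-time
rows). `true_counterfactual()` returns ground truth either by exact
enumeration of all covariate/treatment paths (the discrete `K = 2`
process, 64 paths) or by simulating the true structural equations at large
`s` with a Monte Carlo standard error.

What the generator emulates: longitudinal coding rules (event truncation,
missing outcomes on censored/competing rows), confounding with feedback,
all eight covariate families in at least one process, optional independent
censoring. What it does not emulate: informative censoring, measurement
error, irregular visit times, high-dimensional covariates, and model
misspecification — so passing recovery tests demonstrates correctness of
the estimator under correctly specified models, not robustness on messy
real data.

Validation sizes were chosen to make Monte Carlo error a small fraction of
the tolerances: parameter recovery uses `n = 2500`, `s = 10000` and 20
bootstrap replicates with a three-combined-standard-error criterion
(engine bootstrap SE plus truth MC SE); the enumeration check uses
`s = 100000` against the exact sum with the fitted-model probabilities;
the saturated diagnostic uses `n = 4000`, `s = 100000`.

## Known limitations

* Covariate models are fitted on rows with `k >= 1` because baselines are
  resampled, not simulated; a time-varying coefficient structure across
  `k` must be expressed inside the pooled formulas (e.g. interactions with
  the time index or `categorical_time`).
* The natural course inherits any misspecification of the covariate
  models; the nonparametric benchmarks diagnose but do not correct it.
* Threshold rules on a binary treatment collapse to static rules except
  for the retained natural values.
* No inverse-probability-of-censoring weighting: the nonparametric
  benchmarks assume censoring independent of covariates, and the
  parametric estimates assume the covariate/outcome models hold across the
  censoring pattern.
* Estimates are only as good as positivity allows: strategies far outside
  the observed treatment distribution extrapolate the fitted models, and
  the range clamping makes that extrapolation conservative rather than
  eliminating it.
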
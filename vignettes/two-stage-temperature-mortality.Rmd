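---
title: "Two-stage modelling of temperature-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage modelling of temperature-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempmort)
```

## The problem and the model

Daily mortality responds to ambient temperature non-linearly and with a
delay: cold increases risk for up to three weeks after exposure, heat
acts within days, and the risk is lowest at a location-specific
"optimum" temperature usually well above the median.  Quantifying the
share of deaths attributable to non-optimum temperature across many
locations requires (i) a flexible per-location model of the joint
exposure–lag–response surface, (ii) a way of pooling those surfaces
across locations with very different climates and population sizes, and
(iii) an attribution step that turns a pooled curve into attributable
deaths and fractions.

`tempmort` implements the standard two-stage design used in
multi-country studies of this question.

**First stage.** For each location, daily death counts $Y_t$ are
modelled by a quasi-Poisson regression

$$\log E[Y_t] = \alpha + s(t) + \mathrm{DOW}_t +
  \sum_{l=0}^{21}\, f(x_{t-l}, l),$$

where $s(t)$ is a natural cubic spline of time with 8 df per year
(seasonality and long-term trend), $\mathrm{DOW}_t$ are day-of-week
indicators, and $f(x, l)$ is a distributed lag non-linear model (DLNM)
term: the tensor product (cross-basis) of a quadratic B-spline in
temperature (internal knots at the location's 10th, 75th and 90th
temperature percentiles, boundary knots at its observed range, dimension
$v_x = 5$) and a natural cubic spline in lag over 0–21 days (intercept
plus three internal knots equally spaced on the log-lag scale, dimension
$v_l = 5$).  The variance is $\phi\,\mu$ with $\phi$ estimated from the
Pearson statistic.

**Reduction.** The $v_x \times v_l$ cross-basis coefficients are
collapsed to the *overall cumulative* exposure–response curve by summing
the lag basis over the integer lag grid: $\eta = (I_{v_x} \otimes
c^\top)\,\theta$ with $c_k = \sum_{l=0}^{21} C_k(l)$, and the covariance
transformed by the same linear map.  Daily data make the integer sum
(rather than an integral over lag) the natural cumulation.

**Second stage.** The reduced curves are pooled by a multivariate
random-effects meta-regression $\hat\eta_i \sim N(X_i\beta,\; S_i +
\Psi)$, with meta-predictors (by default) country indicators, the
location average temperature and its range.  $\Psi$ is estimated by
REML, profiling out $\beta$; the optimiser works on the Cholesky factor
of $\Psi$ with a log-diagonal, which enforces positive semidefiniteness
without constraints, and restarts from deterministically perturbed
points if BFGS reports non-convergence.  Heterogeneity is summarised by
the multivariate Cochran $Q$ and $I^2$; predictor blocks are tested by
multivariate Wald statistics.  Best linear unbiased predictions shrink
each location's curve towards its fixed-effect prediction, letting
locations with few deaths borrow strength from the ensemble.

**Attribution.** For each location the minimum-mortality temperature
(MMT) is the grid minimum of the BLUP cumulative curve over the integer
1st–99th empirical percentiles (ties broken towards the median
percentile).  With $b_t$ the cumulative log-RR of day $t$'s temperature
relative to the MMT, the *forward* perspective attributes
$\mathrm{AF}_t = 1 - e^{-b_t}$ of the deaths over days $t..t+21$ to day
$t$'s exposure; attributable numbers are summed over days and divided by
total deaths to give attributable fractions, split by temperature range:
cold/heat at the MMT, extreme/moderate at the 2.5th and 97.5th
percentiles (further percentile cutoffs are optional).  Monte Carlo
empirical confidence intervals resample the BLUP coefficients from their
multivariate normal distribution (MMT held at its point estimate,
1000 draws by default) and take empirical 2.5th/97.5th percentiles of
every aggregated quantity.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| exposure knots | 10/75/90th pct | placement of the quadratic B-spline knots (type-7 quantiles) |
| lag window | 21 days | captures delayed cold effects, excludes pure harvesting |
| lag knots | 3, log-spaced in (1, 21) | more resolution at short lags |
| time spline | 8 df/year, total `round(8 n/365.25)` | seasonality control |
| MMT grid | percentiles 1–99 | search range for the optimum temperature |
| extreme cutoffs | 2.5 / 97.5th pct | extreme vs moderate split |
| `n_sim` | 1000 | Monte Carlo draws for empirical CIs |

All of these sit in a single `pipeline_config()`; a sensitivity analysis
is a one-argument diff of that object.

## The synthetic-data generator

No multi-country mortality registry data are distributable, so the
package ships a generator whose truth is known and whose structure
mirrors the target data: a seasonal sinusoidal temperature (peak
mid-summer) with stationary AR(1) noise; overdispersed counts
(negative-binomial with variance $\phi\mu$, the generative counterpart
of the quasi-Poisson assumption) driven by a separable
exposure–lag–response surface — linear in the cold tail, quadratic in
the heat tail, zero at a true MMT, with fixed non-negative lag weights
summing to one — plus a mild winter-peaking mortality cycle and
day-of-week effects; and location-level heterogeneity (log-normal
perturbations of the slope coefficients, a 1 °C-scale shift of the MMT)
tied to a metadata table of countries, average temperatures and ranges.

Default study conditions, chosen to mirror the regime reported for real
multi-country datasets and then held fixed: 20 locations across 4
countries, 5 years each, baseline 30 deaths/day, mean temperatures
10–16 °C against a true MMT of 19 °C (placing location-specific MMT
percentiles at roughly 62–96, median ≈ 78), seasonal amplitude 8 °C,
AR(1) noise (ρ = 0.6, innovation sd 2 °C), overdispersion 1.3,
cold slope 0.015 and heat coefficient 0.015 (cumulative RR ≈ 1.3–1.5 at
the distribution tails), giving a cold-dominant true total AF ≈ 0.14.

Because the generative model is known, the true attributable fraction
is computed on the expected-death scale with no sampling noise:
$\mathrm{AF} = 1 - \sum_t \mu^0_t / \sum_t \mu^1_t$, where $\mu^1$ is
the factual expected rate and $\mu^0$ holds every day at the true MMT.
The baseline multiplies numerator and denominator and cancels exactly;
day-of-week factors are likewise excluded from the truth functional
(they are risk-ratio factors orthogonal to temperature), making the
stated invariances exact rather than approximate.  Cold and heat
components classify each day's expected excess by that day's temperature
relative to the true MMT, so they sum to the total exactly.

What the generator does *not* emulate: real calendars (it uses 365-day
years; the reader handles true dates), air pollution and humidity
confounding, cause-specific mortality, population trends, missing data,
and multi-station exposure measurement error.  Passing tests therefore
validate the statistical machinery under a correctly specified
(separable, kink-at-MMT) truth — they do not certify performance on
real registry data.

## Numerical choices

- **IRLS**: relative deviance tolerance $10^{-9}$, 50 iterations, exact
  failure on rank-deficient designs (collinear columns are named).
- **REML**: BFGS on the Cholesky parameterisation, objective tolerance
  ~$10^{-10}$, up to five deterministically jittered restarts; the
  starting $\Psi$ is a moment estimate from fixed-effect residuals with
  eigenvalues floored at a small positive value.  Meta-predictors are
  centred/scaled internally and estimates mapped back, for conditioning.
- **Quantiles**: type-7 (linear interpolation) everywhere, so knots and
  percentile cutoffs are reproducible.
- **Edge days**: the first 21 days of a series use truncated lag sums
  (flagged as edge rows) rather than being dropped, keeping the outcome
  alignment; the generator renormalises truncated lag weights for the
  same days.  Forward attribution windows truncated by the series end
  use the mean over available days (an option drops them instead).
- **Log-lag knots** anchor the grid at $\log 1$ (log 0 being undefined)
  — the only reading of "equally spaced on the log scale" consistent
  with a lag range starting at 0.
- **Degenerate inputs**: all-equal temperature series are rejected in
  the MMT search and knot construction; temperatures outside a basis
  boundary are evaluated on the polynomial extension with a warning.
- **Ties** in the MMT grid go to the percentile nearest the median.

## Design choices that were genuinely open

- *Backward perspective.* After reduction, lag-specific contributions
  are no longer identified, so the optional backward attribution spreads
  the overall cumulative log-RR uniformly over the past 22-day exposure
  history.  It is a sensitivity flag, not the default.
- *Truth functional.* The dataset-level true AF uses the aggregate
  counterfactual-ratio form above; the estimator uses the forward
  day-by-day method.  The two agree asymptotically but differ by a few
  tenths of a percentage point at realistic series lengths because they
  weight days differently; end-to-end recovery checks absorb this gap
  in their tolerance.
- *Country medians.* The reported country-level "minimum mortality
  percentile" is the unweighted median across that country's locations.
- *eCI sampling.* BLUP curves across locations are correlated, because
  they share the estimated fixed effects.  The Monte Carlo draws
  therefore perturb the fixed-effect vector once per simulation (shared
  by all locations) and add independent conditional random-effect
  deviations; each location's marginal distribution equals its reported
  BLUP covariance, but country and total aggregates keep the common
  component.  Sampling locations independently instead (available via
  `beta_vcov = NULL`) lets errors cancel in aggregates and shrinks total
  intervals by roughly the square root of the number of locations; in
  calibration simulations the joint scheme achieves near-nominal
  coverage of the true total attributable fraction while the
  independent scheme under-covers.
- *Resumability.* The meta-analysis fit is serialised to JSON and the
  in-memory fit replaced by its serialised round-trip, so a cached
  re-run is bit-identical to the original.

## Validation scale

The test-suite simulations are sized for a desk machine: end-to-end
recovery uses 50 replicates of the default 20-location × 5-year
scenario; interval calibration uses 200 replicates of an 8-location ×
3-year version with 500 Monte Carlo draws; the null (zero-effect)
calibration uses 50 replicates of a 6-location × 2-year version.  These
sizes are stated here as the package's validation design.

## Known limitations

- The quadratic exposure spline cannot represent a sharp kink at the
  MMT exactly; with a kinked truth the fitted curve slightly
  underestimates risk just below the MMT and overestimates it in the
  moderate range, a basis-approximation bias that attribution inherits.
- Wald tests and eCIs ignore the uncertainty of $\hat\Psi$ and of the
  estimated MMT.  Because the MMT is the argmin of the estimated curve,
  the attributable fraction is a non-negatively biased statistic: under
  a true null the point estimate is positive and the coefficient-only
  eCI does not reach zero.  Detecting a null therefore requires testing
  the curve itself (for example a Wald test of $\eta$), not the AF
  interval.
- The first stage assumes exposure is measured without error and that
  seasonal control by the time spline does not absorb genuine
  temperature signal; both are known sources of bias in real data.
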
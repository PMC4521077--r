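# tempmort

Two-stage distributed lag non-linear modelling of the mortality burden
attributable to non-optimum ambient temperature.

## What this package is for

Epidemiologists studying temperature and mortality need to (1) estimate,
per location, how the relative risk of death depends jointly on daily
mean temperature and on the lag since exposure; (2) pool those
location-specific curves across many locations and countries; and
(3) convert the pooled curves into attributable deaths and fractions,
split into cold/heat and moderate/extreme components.  `tempmort`
implements that full workflow for daily time series of death counts and
mean temperature, plus a synthetic-data generator with a known truth for
validating every stage.

## The model in brief

**Stage 1 (per location).** Quasi-Poisson regression

log E[Y_t] = α + s(t) + DOW_t + Σ_{l=0..21} f(x_{t−l}, l)

with a natural cubic time spline `s(t)` (8 df/year), day-of-week
indicators, and a DLNM cross-basis `f`: quadratic B-spline in
temperature (knots at the location's 10th/75th/90th percentiles) ×
natural cubic spline in lag (intercept + 3 log-spaced knots on 0–21
days).  Each fit is reduced to the overall cumulative exposure–response
curve η = (I ⊗ c′)θ with its covariance.

**Stage 2 (across locations).** Multivariate random-effects
meta-regression η̂_i ~ N(X_i β, S_i + Ψ) with REML estimation of the
between-location covariance Ψ, meta-predictors (country, average
temperature, temperature range), multivariate Wald tests, Cochran Q and
I², and best linear unbiased predictions (BLUPs) per location.

**Attribution.** The minimum-mortality temperature (MMT) is the minimum
of each BLUP curve over the 1st–99th percentile grid; forward
attribution assigns `1 − exp(−b_t)` of deaths over days `t..t+21` to day
`t`'s temperature; components are split at the MMT and at the
2.5th/97.5th percentiles; Monte Carlo empirical CIs resample the BLUP
coefficients jointly across locations (the fixed-effect perturbation is
shared; see the methods vignette).

## Worked example

```r
library(tempmort)

# a synthetic 6-location, 3-year study with a known true surface
cfg <- scenario_config(n_locations = 6, years_per_location = 3, seed = 7)
ds  <- generate_dataset(cfg)
dir <- tempfile(); write_dataset(ds, dir)

res <- run_pipeline(pipeline_config(dir, out_dir = tempfile(),
                                    n_sim = 200, seed = 3,
                                    predictors = "avg_tmean"))
round(100 * unlist(res$point$total[c("af_total", "af_cold", "af_heat")]), 2)
#> af_total  af_cold  af_heat
#>     9.46     5.10     4.35
round(100 * unlist(ds$true_af[c("total", "cold", "heat")]), 2)
#> total  cold  heat
#> 14.66 10.83  3.82
res$metafit$I2
#> [1] 50.58686
sapply(res$mmt, `[[`, "mmt_percentile")
#> [1] 53 91 42 76 65 39
```

The estimated total attributable fraction (9.5% of all deaths, mostly
cold) is read against the generator's exact truth (14.7%); a 6-location
× 3-year study is deliberately small, so the point estimate sits well
inside its wide empirical interval (`res$eci`) and the per-location MMT
percentiles are noisy.  `export_figures(res)` writes per-location
RR-curve CSVs with the MMT and extreme-percentile markers.

A command-line front end with `simulate`, `run` and `report`
subcommands is installed at `inst/cli/tempmort-cli.R`:

```sh
Rscript inst/cli/tempmort-cli.R simulate --out data/ --locations 20 --years 5 --seed 1
Rscript inst/cli/tempmort-cli.R run --data data/ --out run1/ --n-sim 1000 --seed 1
```

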
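# Synthetic multi-location daily temperature/mortality data with a known
# separable exposure-lag-response surface, so that the true attributable
# fraction is available in closed form on the expected-death scale.

# Generator constants shared between the mortality simulator and the
# truth functional: a mild winter-peaking seasonal cycle on the log rate
# and small day-of-week effects (Monday reference).
MORT_SEAS_AMP <- 0.08
DOW_EFFECTS <- c(0, -0.01, -0.01, 0, 0.01, 0.02, 0.03)

mort_seasonal <- function(day_index) {
  doy <- ((day_index - 1L) %% 365L) + 1L
  MORT_SEAS_AMP * cos(2 * pi * (doy - 15) / 365)
}

#' True exposure-lag-response surface
#'
#' Separable surface `w_l * f(x)` with `f` zero at the true
#' minimum-mortality temperature, linear in the cold tail
#' (`cold_slope * (mmt - x)` below the MMT, log-RR per degree C,
#' cumulative over lags) and quadratic in the heat tail
#' (`heat_coef * (x - mmt)^2` above it), mimicking the near-linear cold
#' and steep supralinear heat responses seen in multi-country analyses.
#' The lag weights are non-negative and sum to one over lags 0..21, so
#' `f` is directly the overall cumulative log-RR.
#'
#' @param mmt_true true minimum-mortality temperature (degrees C).
#' @param cold_slope cumulative log-RR per degree C below `mmt_true`.
#' @param heat_coef cumulative quadratic coefficient above `mmt_true`.
#' @param lag_weights 22 non-negative weights over lags 0..21 summing to
#'   1; the default decays exponentially (mean lag about 6 days).
#' @return object of class `true_surface`.
#' @export
true_surface <- function(mmt_true = 19, cold_slope = 0.015,
                         heat_coef = 0.015,
                         lag_weights = {
                           w <- exp(-(0:21) / 7); w / sum(w)
                         }) {
  lag_weights <- as.numeric(lag_weights)
  if (length(lag_weights) != 22) stop("'lag_weights' must have length 22")
  if (any(lag_weights < 0)) stop("'lag_weights' must be non-negative")
  if (abs(sum(lag_weights) - 1) > 1e-12)
    stop("'lag_weights' must sum to 1")
  structure(list(mmt_true = mmt_true, cold_slope = cold_slope,
                 heat_coef = heat_coef, lag_weights = lag_weights),
            class = "true_surface")
}

# Overall cumulative log-RR of the true surface at temperature x.
surface_logrr <- function(surface, x) {
  ifelse(x < surface$mmt_true,
         surface$cold_slope * (surface$mmt_true - x),
         surface$heat_coef * (x - surface$mmt_true)^2)
}

# Lag-distributed log-RR series: sum_l w_l f(x[t-l]), with the first 21
# days using renormalised truncated weights.
lagged_logrr <- function(fx, lag_weights) {
  n <- length(fx)
  L <- length(lag_weights) - 1L
  b <- as.numeric(stats::filter(fx, lag_weights, sides = 1))
  for (t in seq_len(min(L, n))) {
    w <- lag_weights[seq_len(t)]
    b[t] <- sum(w * fx[t:1]) / sum(w)
  }
  b
}

#' Scenario configuration for the synthetic-data generator
#'
#' Defines a multi-location study: per-location study length, countries,
#' baseline mortality, the seasonal/autoregressive temperature process,
#' mortality overdispersion, the true surface, and the between-location
#' heterogeneity of the surface.  Scalars for `baseline_deaths`,
#' `temp_mean` and `temp_amplitude` are recycled across locations.  The
#' defaults describe a 20-location, 5-year study across 4 synthetic
#' countries with location mean temperatures spanning 8-24 degrees C.
#'
#' @param n_locations number of locations (>= 1).
#' @param years_per_location study length per location (365-day years).
#' @param country_labels country label per location.
#' @param baseline_deaths expected deaths/day per location.
#' @param temp_mean annual mean temperature per location (degrees C).
#' @param temp_amplitude seasonal half-range (degrees C, >= 0).
#' @param temp_ar_rho AR(1) coefficient of the temperature noise, |rho| < 1.
#' @param temp_noise_sd innovation standard deviation of the AR(1) noise.
#' @param overdispersion variance inflation of the counts (>= 1; 1 =
#'   Poisson).
#' @param surface_params a [true_surface()].
#' @param heterogeneity_sd standard deviation of the location-level
#'   random perturbation of the surface (log scale for the slope
#'   coefficients; `10 * heterogeneity_sd` degrees C for the MMT).
#' @param seed integer master seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_locations = 20L, years_per_location = 5L,
                            country_labels = rep(paste0("Country",
                                                        LETTERS[1:4]),
                                                 length.out = n_locations),
                            baseline_deaths = 30,
                            temp_mean = seq(10, 16,
                                            length.out = n_locations),
                            temp_amplitude = 8, temp_ar_rho = 0.6,
                            temp_noise_sd = 2, overdispersion = 1.3,
                            surface_params = true_surface(),
                            heterogeneity_sd = 0.1, seed = 42L) {
  if (n_locations < 1) stop("'n_locations' must be >= 1")
  if (years_per_location < 1) stop("'years_per_location' must be positive")
  if (length(country_labels) != n_locations)
    stop("'country_labels' must have length n_locations")
  if (any(baseline_deaths <= 0)) stop("'baseline_deaths' must be positive")
  if (any(temp_amplitude < 0)) stop("'temp_amplitude' must be >= 0")
  if (abs(temp_ar_rho) >= 1) stop("'temp_ar_rho' must satisfy |rho| < 1")
  if (overdispersion < 1) stop("'overdispersion' must be >= 1")
  stopifnot(inherits(surface_params, "true_surface"))
  structure(list(
    n_locations = as.integer(n_locations),
    years_per_location = as.integer(years_per_location),
    country_labels = as.character(country_labels),
    baseline_deaths = rep_len(baseline_deaths, n_locations),
    temp_mean = rep_len(temp_mean, n_locations),
    temp_amplitude = rep_len(temp_amplitude, n_locations),
    temp_ar_rho = temp_ar_rho, temp_noise_sd = temp_noise_sd,
    overdispersion = overdispersion, surface_params = surface_params,
    heterogeneity_sd = heterogeneity_sd, seed = as.integer(seed)),
    class = "scenario_config")
}

#' Generate one location's daily temperature series
#'
#' Annual sinusoid (mean `temp_mean`, half-range `temp_amplitude`,
#' peaking mid-summer around day 196 of a 365-day year) plus stationary
#' AR(1) Gaussian noise.  Reproducible from the configuration seed and
#' the location index.
#'
#' @param config a [scenario_config()].
#' @param location_index location number in `1..n_locations`.
#' @return numeric vector of `365 * years_per_location` daily
#'   temperatures (degrees C).
#' @export
generate_temperature <- function(config, location_index = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  if (location_index < 1 || location_index > config$n_locations)
    stop("'location_index' out of range")
  if (config$years_per_location < 1) stop("non-positive study length")
  n <- 365L * config$years_per_location
  doy <- ((seq_len(n) - 1L) %% 365L) + 1L
  seasonal <- config$temp_mean[location_index] +
    config$temp_amplitude[location_index] * cos(2 * pi * (doy - 196) / 365)
  set.seed(stream_seed(config$seed, location_index))
  rho <- config$temp_ar_rho
  sdn <- config$temp_noise_sd
  if (sdn > 0) {
    z0 <- rnorm(1, 0, sdn / sqrt(1 - rho^2))
    e <- rnorm(n, 0, sdn)
    noise <- as.numeric(stats::filter(e, rho, method = "recursive",
                                      init = z0))
  } else noise <- numeric(n)
  seasonal + noise
}

#' Generate daily death counts for one location
#'
#' Log expected deaths are the sum of the log baseline, a mild
#' winter-peaking seasonal cycle, day-of-week effects, and the
#' lag-distributed temperature effect `sum_l w_l f(x[t-l])` of the true
#' surface (truncated lag sums renormalised over the first 21 days).
#' Counts are negative-binomial with variance `mu * overdispersion`
#' (Poisson when `overdispersion = 1`), the generative counterpart of the
#' quasi-Poisson mean-variance assumption.
#'
#' @param temps daily temperature vector (length >= 22).
#' @param config a [scenario_config()].
#' @param surface a [true_surface()]; defaults to the configured one.
#' @param location_index used for the baseline and the random stream.
#' @param seed optional override of the derived stream seed.
#' @return integer vector of daily death counts.
#' @export
generate_mortality <- function(temps, config, surface = config$surface_params,
                               location_index = 1L, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(surface, "true_surface"))
  if (length(temps) < 22) stop("'temps' must cover at least 22 days")
  baseline <- config$baseline_deaths[min(location_index,
                                         length(config$baseline_deaths))]
  if (baseline <= 0) stop("non-positive baseline death rate")
  n <- length(temps)
  b <- lagged_logrr(surface_logrr(surface, temps), surface$lag_weights)
  dow <- DOW_EFFECTS[((seq_len(n) - 1L) %% 7L) + 1L]
  mu <- exp(log(baseline) + mort_seasonal(seq_len(n)) + dow + b)
  if (is.null(seed)) seed <- stream_seed(config$seed, 1000L + location_index)
  set.seed(seed)
  phi <- config$overdispersion
  if (phi == 1) {
    rpois(n, mu)
  } else {
    rnbinom(n, mu = mu, size = mu / (phi - 1))
  }
}

#' True attributable fraction of the generative model
#'
#' Computed on the expected-death scale, so it carries no sampling noise:
#' with factual rates `mu1_t = exp(s_t + b_t)` (seasonal cycle plus the
#' lag-distributed temperature effect) and counterfactual rates
#' `mu0_t = exp(s_t)` obtained by holding every day at the true MMT, the
#' total attributable fraction is `1 - sum(mu0) / sum(mu1)`.  The
#' baseline rate and day-of-week factors multiply numerator and
#' denominator equally and are omitted, making the fraction exactly
#' invariant to them.  Cold and heat components assign each day's excess
#' `mu1_t - mu0_t` by the day's temperature relative to the true MMT, so
#' the two components sum to the total exactly.
#'
#' @param temps daily temperature vector.
#' @param surface the [true_surface()] that generated the series.
#' @param baseline optional expected deaths/day, used only to weight
#'   locations when aggregating across a dataset.
#' @return list with `total`, `cold`, `heat` (fractions), and the
#'   weighted sums `expected_deaths`, `excess_total`, `excess_cold`,
#'   `excess_heat` used for aggregation.
#' @export
true_attributable_fraction <- function(temps, surface, baseline = 1) {
  if (missing(surface) || !inherits(surface, "true_surface"))
    stop("a 'true_surface' is required")
  n <- length(temps)
  b <- lagged_logrr(surface_logrr(surface, temps), surface$lag_weights)
  s <- mort_seasonal(seq_len(n))
  mu1 <- baseline * exp(s + b)
  mu0 <- baseline * exp(s)
  excess <- mu1 - mu0
  cold <- temps < surface$mmt_true
  list(total = 1 - sum(mu0) / sum(mu1),
       cold = sum(excess[cold]) / sum(mu1),
       heat = sum(excess[!cold]) / sum(mu1),
       expected_deaths = sum(mu1),
       excess_total = sum(excess),
       excess_cold = sum(excess[cold]),
       excess_heat = sum(excess[!cold]))
}

#' Generate a full synthetic multi-location dataset
#'
#' Draws per-location temperature and mortality series with the surface
#' coefficients perturbed by location-level random effects (log-normal
#' multiplicative on the cold slope and heat coefficient, additive on the
#' MMT), assembles the per-location metadata used as meta-predictors
#' (country, average temperature, temperature range), and attaches the
#' per-location truth together with the dataset-level true attributable
#' fractions (expected-death weighted across locations).
#'
#' @param config a [scenario_config()].
#' @return object of class `synthetic_dataset` with elements `series`
#'   (list of data frames with `date`, `deaths`, `tmean`), `metadata`,
#'   `truth` (list of per-location `true_surface`), `true_af`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n_loc <- config$n_locations
  if (length(config$country_labels) != n_loc)
    stop("'country_labels' must have one entry per location")
  surf0 <- config$surface_params
  set.seed(stream_seed(config$seed, 999999L))
  hsd <- config$heterogeneity_sd
  truth <- lapply(seq_len(n_loc), function(i) {
    z <- rnorm(3, 0, hsd)
    true_surface(mmt_true = surf0$mmt_true + 10 * z[3],
                 cold_slope = surf0$cold_slope * exp(z[1]),
                 heat_coef = surf0$heat_coef * exp(z[2]),
                 lag_weights = surf0$lag_weights)
  })
  n_days <- 365L * config$years_per_location
  dates <- seq(as.Date("2001-01-01"), by = "day", length.out = n_days)
  series <- vector("list", n_loc)
  af_rows <- vector("list", n_loc)
  loc_ids <- sprintf("loc%03d", seq_len(n_loc))
  for (i in seq_len(n_loc)) {
    temps <- generate_temperature(config, i)
    deaths <- generate_mortality(temps, config, truth[[i]],
                                 location_index = i)
    series[[i]] <- data.frame(date = dates, deaths = deaths, tmean = temps)
    af_rows[[i]] <- true_attributable_fraction(
      temps, truth[[i]], baseline = config$baseline_deaths[i])
  }
  metadata <- data.frame(
    location = loc_ids,
    country = config$country_labels,
    avg_tmean = vapply(series, function(s) mean(s$tmean), 0),
    range_tmean = vapply(series, function(s) diff(range(s$tmean)), 0))
  per_loc <- data.frame(
    location = loc_ids,
    total = vapply(af_rows, `[[`, 0, "total"),
    cold = vapply(af_rows, `[[`, 0, "cold"),
    heat = vapply(af_rows, `[[`, 0, "heat"))
  ed <- vapply(af_rows, `[[`, 0, "expected_deaths")
  true_af <- list(
    per_location = per_loc,
    total = sum(vapply(af_rows, `[[`, 0, "excess_total")) / sum(ed),
    cold = sum(vapply(af_rows, `[[`, 0, "excess_cold")) / sum(ed),
    heat = sum(vapply(af_rows, `[[`, 0, "excess_heat")) / sum(ed),
    mmt_true = vapply(truth, `[[`, 0, "mmt_true"))
  names(series) <- loc_ids
  structure(list(series = series, metadata = metadata, truth = truth,
                 true_af = true_af, config = config),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to CSV files
#'
#' Emits one CSV per location with columns `date` (ISO-8601), `deaths`,
#' `tmean`, plus a `metadata.csv` with columns `location`, `country`,
#' `avg_tmean`, `range_tmean` -- the exact dialect [read_locations()]
#' consumes.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (loc in names(dataset$series)) {
    s <- dataset$series[[loc]]
    s$date <- format(s$date, "%Y-%m-%d")
    write.csv(s, file.path(dir, paste0(loc, ".csv")), row.names = FALSE)
  }
  write.csv(dataset$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE)
  invisible(dir)
}
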
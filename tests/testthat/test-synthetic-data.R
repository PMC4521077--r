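test_that("temperature generator: degenerate, deterministic, AR(1) structure", {
  cfg0 <- scenario_config(n_locations = 1, years_per_location = 1,
                          country_labels = "A", temp_mean = 12,
                          temp_amplitude = 0, temp_noise_sd = 0, seed = 1)
  expect_equal(generate_temperature(cfg0, 1), rep(12, 365))
  cfg <- tiny_config()
  expect_identical(generate_temperature(cfg, 1), generate_temperature(cfg, 1))
  expect_false(identical(generate_temperature(cfg, 1),
                         generate_temperature(cfg, 2)))
  # lag-1 autocorrelation of the de-seasonalised series near rho
  cfga <- scenario_config(n_locations = 1, years_per_location = 28,
                          country_labels = "A", temp_mean = 12,
                          temp_ar_rho = 0.7, temp_noise_sd = 2, seed = 9)
  temps <- generate_temperature(cfga, 1)
  n <- length(temps)
  doy <- ((seq_len(n) - 1) %% 365) + 1
  seasonal <- 12 + cfga$temp_amplitude[1] * cos(2 * pi * (doy - 196) / 365)
  z <- temps - seasonal
  r1 <- cor(z[-1], z[-n])
  expect_lt(abs(r1 - 0.7), 0.05)
})

test_that("mortality generator moments match the configured model", {
  # null surface: counts uncorrelated with temperature (temperature
  # seasonality switched off so the only possible channel is the surface;
  # with it on, deaths and temperature share the seasonal cycle)
  cfg <- scenario_config(n_locations = 1, years_per_location = 20,
                         country_labels = "A", temp_mean = 13,
                         temp_amplitude = 0,
                         surface_params = true_surface(cold_slope = 0,
                                                       heat_coef = 0),
                         heterogeneity_sd = 0, seed = 2)
  temps <- generate_temperature(cfg, 1)
  deaths <- generate_mortality(temps, cfg, location_index = 1)
  expect_lt(abs(cor(deaths, temps)), 3 / sqrt(length(temps)) + 0.02)
  expect_true(all(deaths >= 0 & deaths == round(deaths)))
  # Poisson limit: sample mean near the constant baseline
  cfgp <- scenario_config(n_locations = 1, years_per_location = 10,
                          country_labels = "A", baseline_deaths = 50,
                          temp_mean = 19, temp_amplitude = 0,
                          temp_noise_sd = 0, overdispersion = 1,
                          surface_params = true_surface(cold_slope = 0,
                                                        heat_coef = 0),
                          heterogeneity_sd = 0, seed = 3)
  tp <- generate_temperature(cfgp, 1)
  dp <- generate_mortality(tp, cfgp, location_index = 1)
  n <- length(dp)
  mu <- 50 * exp(mort_seas_dow_offset(n))
  expect_lt(abs(mean(dp) - mean(mu)), 3 * sqrt(mean(mu) / n))
  # variance/mean ratio near the configured overdispersion
  cfgo <- scenario_config(n_locations = 1, years_per_location = 274,
                          country_labels = "A", baseline_deaths = 30,
                          temp_mean = 19, temp_amplitude = 0,
                          temp_noise_sd = 0, overdispersion = 1.5,
                          surface_params = true_surface(cold_slope = 0,
                                                        heat_coef = 0),
                          heterogeneity_sd = 0, seed = 4)
  to <- generate_temperature(cfgo, 1)     # 100 010 constant days
  do <- generate_mortality(to, cfgo, location_index = 1)
  mu_o <- 30 * exp(mort_seas_dow_offset(length(do)))
  ratio <- mean((do - mu_o)^2 / mu_o)
  expect_lt(abs(ratio - 1.5) / 1.5, 0.10)
})

test_that("true attributable fraction has its closed-form limits", {
  surf <- true_surface()
  # all days at the true MMT: zero AF
  af0 <- true_attributable_fraction(rep(surf$mmt_true, 400), surf)
  expect_equal(af0$total, 0)
  # null surface: zero AF whatever the series
  afn <- true_attributable_fraction(runif(400, 0, 30),
                                    true_surface(cold_slope = 0,
                                                 heat_coef = 0))
  expect_equal(afn$total, 0)
  # constant cumulative log-RR log(2): AF = 1 - 1/2 exactly
  x2 <- surf$mmt_true - log(2) / surf$cold_slope
  af2 <- true_attributable_fraction(rep(x2, 600), surf)
  expect_equal(af2$total, 0.5, tolerance = 1e-12)
  # invariant to the baseline scale; components add up exactly
  temps <- 14 + 8 * cos(2 * pi * (1:730) / 365) + rnorm(730)
  a1 <- true_attributable_fraction(temps, surf, baseline = 1)
  a2 <- true_attributable_fraction(temps, surf, baseline = 137)
  expect_lt(abs(a1$total - a2$total), 1e-10)
  expect_equal(a1$cold + a1$heat, a1$total, tolerance = 1e-12)
  expect_error(true_attributable_fraction(temps, "nope"), "true_surface")
})

test_that("surface validation enforces the lag-weight invariants", {
  expect_error(true_surface(lag_weights = rep(1 / 21, 21)), "length 22")
  expect_error(true_surface(lag_weights = c(rep(0.05, 21), -0.05)),
               "non-negative")
  expect_error(true_surface(lag_weights = rep(0.05, 22)), "sum to 1")
  expect_equal(sum(true_surface()$lag_weights), 1, tolerance = 1e-12)
})

test_that("dataset generation is deterministic with coherent structure", {
  cfg13 <- scenario_config(n_locations = 13, years_per_location = 1,
                           country_labels = paste0("C", 1:13),
                           heterogeneity_sd = 0, seed = 8)
  ds <- generate_dataset(cfg13)
  expect_length(ds$series, 13)
  expect_equal(length(unique(ds$metadata$country)), 13)
  expect_equal(nrow(ds$metadata), 13)
  expect_length(ds$truth, 13)
  # zero heterogeneity: all locations share the configured surface
  for (s in ds$truth) expect_equal(unclass(s), unclass(cfg13$surface_params))
  ds2 <- generate_dataset(cfg13)
  expect_identical(ds, ds2)
  expect_error(generate_dataset(
    scenario_config(n_locations = 3, country_labels = c("A", "B"))),
    "length n_locations")
})

test_that("dataset CSV export uses the dialect the reader consumes", {
  ds <- generate_dataset(tiny_config())
  dir <- tempfile()
  write_dataset(ds, dir)
  inp <- read_locations(dir)
  expect_equal(names(inp$series), names(ds$series))
  expect_equal(inp$series[[1]]$deaths, ds$series[[1]]$deaths)
  expect_equal(inp$series[[1]]$tmean, ds$series[[1]]$tmean,
               tolerance = 1e-12)
})
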
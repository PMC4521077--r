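# Shared small fixtures, built in code.

# Tiny single-location scenario for first-stage tests.
tiny_config <- function(seed = 11, ...) {
  scenario_config(n_locations = 2, years_per_location = 2,
                  country_labels = c("A", "B"), seed = seed, ...)
}

# A fitted location plus its reduction, cached per test file run.
tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_config()
      ds <- generate_dataset(cfg)
      fit <- fit_location(ds$series[[1]])
      cache <<- list(ds = ds, fit = fit,
                     curve = reduce_to_overall(fit, location = "loc001"))
    }
    cache
  }
})

# Hand-built reduced curves for meta-analysis tests (known values).
make_curve <- function(eta, vcov, espec = NULL, location = NA) {
  structure(list(eta = eta, vcov = as.matrix(vcov), espec = espec,
                 location = location),
            class = "reduced_curve")
}

# Expected log-rate offset (seasonal + day-of-week) of the mortality
# generator, for moment checks.
mort_seas_dow_offset <- function(n) {
  tempmort:::mort_seasonal(seq_len(n)) +
    tempmort:::DOW_EFFECTS[((seq_len(n) - 1L) %% 7L) + 1L]
}

# Minimal mvmeta_fit stub for exercising BLUP/Wald algebra at fixed Psi.
make_metafit <- function(beta, vcov, Psi, y, S, X) {
  structure(list(beta = beta, vcov = vcov, Psi = Psi, k = ncol(y),
                 p = ncol(X), y = y, S = S, X = X, method = "reml"),
            class = "mvmeta_fit")
}
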
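# Small shared helpers.

# Error unless m is a symmetric positive semidefinite matrix.
check_psd <- function(m, name = "matrix", tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-6))
    stop("'", name, "' must be symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1))
    stop("'", name, "' is not positive semidefinite")
  invisible(TRUE)
}

# Symmetrise a nearly symmetric matrix.
symm <- function(m) (m + t(m)) / 2

# Location-specific empirical percentile grid (type-7 quantiles).
percentile_grid <- function(temps, percentiles) {
  quantile(temps, percentiles / 100, type = 7, names = FALSE)
}

# Derive a 32-bit-safe stream seed from a base seed and a stream index.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 104729) %% 2147483647)
}
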
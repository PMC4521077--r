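# Attribution: minimum-mortality temperature, forward-perspective
# attributable deaths/fractions by temperature range, Monte Carlo
# empirical confidence intervals.

#' Find the minimum-mortality temperature
#'
#' Evaluates the overall cumulative log relative risk (internal reference
#' arbitrary -- the argmin is invariant to re-centring) on the grid of the
#' 1st-99th integer empirical percentiles of the location's temperatures
#' and returns the minimising percentile and temperature.  Ties are broken
#' towards the median percentile.
#'
#' @param curve a `reduced_curve`/`blup_curve` with an exposure spec.
#' @param temps the location's daily temperatures (at least 100 values).
#' @param grid integer percentiles to search (default `1:99`).
#' @return object of class `mmt_result` with elements `mmt`,
#'   `mmt_percentile`, and the search `grid` (percentile/temperature
#'   pairs with the cumulative log-RR profile).
#' @export
find_mmt <- function(curve, temps, grid = 1:99) {
  temps <- temps[is.finite(temps)]
  if (length(temps) < 100) stop("need at least 100 temperature observations")
  if (diff(range(temps)) == 0)
    stop("degenerate temperature distribution (all values equal)")
  tg <- percentile_grid(temps, grid)
  B <- exposure_basis(tg, curve$espec)
  val <- drop(B %*% curve$eta)
  cand <- which(val <= min(val) + 1e-12)
  pick <- cand[order(abs(grid[cand] - 50), grid[cand])][1]
  structure(list(mmt = tg[pick], mmt_percentile = grid[pick],
                 grid = data.frame(percentile = grid, temperature = tg,
                                   logrr = val - val[pick])),
            class = "mmt_result")
}

#' Temperature percentile cutoffs for component attribution
#'
#' Per-location temperatures at the requested percentile cutpoints.  The
#' 2.5th and 97.5th percentiles (defining extreme cold and extreme heat)
#' are always included; further cutpoints (for example 10, 25, 50, 75, 90)
#' may be added for finer range tables.
#'
#' @param temps daily temperature vector.
#' @param extra additional percentile cutpoints in (0, 100).
#' @return object of class `range_cutoffs`: data frame with columns
#'   `percentile`, `temperature`, sorted by percentile.
#' @export
range_cutoffs <- function(temps, extra = numeric(0)) {
  pct <- sort(unique(c(2.5, 97.5, extra)))
  if (any(pct <= 0 | pct >= 100)) stop("cutoffs must lie strictly in (0, 100)")
  tv <- percentile_grid(temps[is.finite(temps)], pct)
  if (is.unsorted(tv)) stop("cutoff temperatures are not non-decreasing")
  structure(data.frame(percentile = pct, temperature = tv),
            class = c("range_cutoffs", "data.frame"))
}

#' Daily overall cumulative log relative risk, centred at the MMT
#'
#' `b_t = [R(x_t) - R(mmt)]' eta`, so days at the minimum-mortality
#' temperature have exactly zero log-RR.  Temperatures outside the
#' exposure-basis boundary are evaluated on the extended basis with a
#' warning.
#'
#' @param temps daily temperature vector.
#' @param curve `reduced_curve`/`blup_curve` with exposure spec.
#' @param mmt an `mmt_result` or a single reference temperature.
#' @return numeric vector of daily cumulative log-RR values.
#' @export
cumulative_logrr_series <- function(temps, curve, mmt) {
  ref <- if (inherits(mmt, "mmt_result")) mmt$mmt else as.numeric(mmt)
  bd <- curve$espec$boundary
  if (any(temps < bd[1] | temps > bd[2]))
    warning(sum(temps < bd[1] | temps > bd[2]),
            " temperature(s) outside the exposure basis boundary; extended basis used")
  B <- exposure_basis(temps, curve$espec)
  Bref <- exposure_basis(ref, curve$espec)
  drop((B - matrix(Bref, nrow(B), ncol(B), byrow = TRUE)) %*% curve$eta)
}

# Mean of deaths over the forward window t..t+L (available days only).
forward_window_means <- function(deaths, L = 21L) {
  n <- length(deaths)
  cs <- cumsum(c(0, deaths))
  upper <- pmin(seq_len(n) + L, n)
  (cs[upper + 1] - cs[seq_len(n)]) / (upper - seq_len(n) + 1)
}

#' Forward-perspective attributable deaths and fraction
#'
#' For each day, the fraction of deaths over the next `L + 1` days
#' attributable to that day's temperature is `AF_t = 1 - exp(-b_t)`, with
#' `b_t` the overall cumulative log-RR at the day's temperature relative
#' to the MMT; the attributable number is `AN_t = AF_t * mean(deaths over
#' t..t+L)`.  Totals are sums over all days of the series and the total
#' attributable fraction is `AN_total / sum(deaths)`.  Windows truncated
#' by the series end use the mean over available days by default; they
#' can instead be dropped.  A backward perspective (the day's deaths
#' weighted by the average cumulative log-RR of its exposure history) is
#' available for sensitivity analysis.
#'
#' @param series data frame with columns `deaths` and `tmean` (and
#'   optionally `date`).
#' @param curve `reduced_curve`/`blup_curve`.
#' @param mmt `mmt_result` or reference temperature.
#' @param lag maximum lag of the forward window (days).
#' @param perspective `"forward"` (default) or `"backward"`.
#' @param incomplete `"mean"` (default: truncated windows use available
#'   days) or `"drop"` (days with truncated windows contribute no AN).
#' @return list with `an` (per-day attributable numbers), `af_day`
#'   (per-day attributable fractions), `an_total`, `af_total`,
#'   `deaths_total`.
#' @export
attributable_forward <- function(series, curve, mmt, lag = 21L,
                                 perspective = c("forward", "backward"),
                                 incomplete = c("mean", "drop")) {
  perspective <- match.arg(perspective)
  incomplete <- match.arg(incomplete)
  n <- nrow(series)
  if (!n) stop("empty series")
  b <- cumulative_logrr_series(series$tmean, curve, mmt)
  if (perspective == "forward") {
    af_day <- 1 - exp(-b)
    w <- forward_window_means(series$deaths, lag)
    an <- af_day * w
    if (incomplete == "drop" && n > lag)
      an[(n - lag + 1):n] <- 0
  } else {
    # exposure history enters through the mean cumulative log-RR of the
    # past window (uniform spread of the reduced cumulative curve)
    bh <- rev(forward_window_means(rev(b), lag))
    af_day <- 1 - exp(-bh)
    an <- af_day * series$deaths
    if (incomplete == "drop" && n > lag) an[seq_len(lag)] <- 0
  }
  deaths_total <- sum(series$deaths)
  list(an = an, af_day = af_day, an_total = sum(an),
       af_total = sum(an) / deaths_total, deaths_total = deaths_total)
}

#' Split attributable numbers into temperature-range components
#'
#' Assigns each day's attributable number to exactly one bin relative to
#' the MMT and the cutoff temperatures: cold (below MMT) versus heat (at
#' or above), each split into extreme (beyond the 2.5th/97.5th
#' percentile) and moderate parts.  The component sums partition the
#' total exactly.  When `cutoffs` carries additional percentiles, a
#' per-range table over consecutive cutpoints is attached.
#'
#' @param an per-day attributable numbers.
#' @param temps aligned daily temperatures.
#' @param mmt `mmt_result` or reference temperature.
#' @param cutoffs a [range_cutoffs()] object for the same location.
#' @param deaths_total total deaths, used to report attributable
#'   fractions alongside numbers (optional).
#' @return named list of component AN sums (`total`, `cold`, `heat`,
#'   `extreme_cold`, `moderate_cold`, `moderate_heat`, `extreme_heat`),
#'   with an `af` element when `deaths_total` is given and a `ranges`
#'   data frame when extra cutoffs are present.
#' @export
split_components <- function(an, temps, mmt, cutoffs, deaths_total = NULL) {
  stopifnot(length(an) == length(temps))
  ref <- if (inherits(mmt, "mmt_result")) mmt$mmt else as.numeric(mmt)
  qlo <- cutoffs$temperature[cutoffs$percentile == 2.5]
  qhi <- cutoffs$temperature[cutoffs$percentile == 97.5]
  cold <- temps < ref
  masks <- list(total = rep(TRUE, length(an)),
                cold = cold,
                heat = !cold,
                extreme_cold = cold & temps < qlo,
                moderate_cold = cold & temps >= qlo,
                moderate_heat = !cold & temps <= qhi,
                extreme_heat = !cold & temps > qhi)
  out <- lapply(masks, function(m) sum(an[m]))
  extra <- setdiff(cutoffs$percentile, c(2.5, 97.5))
  if (length(extra)) {
    edges <- c(-Inf, cutoffs$temperature, Inf)
    labs <- c(paste0("< p", cutoffs$percentile[1]),
              paste0("p", head(cutoffs$percentile, -1), "-p",
                     tail(cutoffs$percentile, -1)),
              paste0("> p", tail(cutoffs$percentile, 1)))
    bin <- findInterval(temps, cutoffs$temperature,
                        left.open = FALSE) + 1L
    out$ranges <- data.frame(
      range = labs,
      an = vapply(seq_along(labs), function(k) sum(an[bin == k]), 0))
    if (!is.null(deaths_total))
      out$ranges$af <- out$ranges$an / deaths_total
  }
  if (!is.null(deaths_total)) {
    comp <- c("total", "cold", "heat", "extreme_cold", "moderate_cold",
              "moderate_heat", "extreme_heat")
    out$af <- vapply(out[comp], function(a) a / deaths_total, 0)
  }
  out
}

# Fixed component order used throughout attribution outputs.
attr_components <- c("total", "cold", "heat", "extreme_cold",
                     "moderate_cold", "moderate_heat", "extreme_heat")

# Component masks for one location (days x component logical matrix).
component_masks <- function(temps, ref, qlo, qhi) {
  cold <- temps < ref
  cbind(total = rep(TRUE, length(temps)),
        cold = cold, heat = !cold,
        extreme_cold = cold & temps < qlo,
        moderate_cold = cold & temps >= qlo,
        moderate_heat = !cold & temps <= qhi,
        extreme_heat = !cold & temps > qhi)
}

#' Monte Carlo empirical confidence intervals for attributable burdens
#'
#' Propagates the uncertainty of the (BLUP) reduced coefficients into the
#' attributable numbers and fractions: for each simulation every
#' location's coefficient vector is drawn from a multivariate normal
#' centred at its point estimate with the curve's covariance, all
#' component attributable numbers are recomputed with the MMT held at its
#' point estimate, sums are aggregated within country and overall, and
#' the bounds are the empirical 2.5th and 97.5th percentiles across
#' simulations.  Deterministic given `seed`.
#'
#' When `beta_vcov` is supplied and the curves carry the fixed-effect
#' Jacobians from [compute_blups()], the draws are *jointly* sampled:
#' each simulation perturbs the meta-regression fixed effects once,
#' shared by every location, and adds independent conditional
#' random-effect deviations.  Each location's marginal distribution is
#' unchanged, but the cross-location correlation induced by the common
#' fixed-effect estimate is preserved -- without it, location errors
#' cancel in country and total aggregates and the intervals are too
#' narrow.  With `beta_vcov = NULL` locations are drawn independently
#' (the simpler, anti-conservative variant, kept for sensitivity).
#'
#' @param series_list list of per-location data frames (`deaths`,
#'   `tmean`).
#' @param curves list of `blup_curve` (or `reduced_curve`) objects.
#' @param mmts list of `mmt_result` objects (point estimates).
#' @param countries character vector of country labels per location.
#' @param cutoffs_list list of [range_cutoffs()] per location; computed
#'   from each location's temperatures when `NULL`.
#' @param n_sim number of simulations (at least 100; default 1000).
#' @param seed integer seed for the coefficient draws.
#' @param lag forward-window length in days.
#' @param beta_vcov covariance of the meta-regression fixed effects
#'   (`fit$vcov` from [fit_mvmeta()]) enabling joint sampling; `NULL`
#'   for independent per-location draws.
#' @return list with data frames `location`, `country`, `total`, each
#'   holding `an_low/an_high/af_low/af_high` per component, plus
#'   `n_sim` and `seed`.
#' @export
monte_carlo_eci <- function(series_list, curves, mmts, countries,
                            cutoffs_list = NULL, n_sim = 1000L, seed = 1L,
                            lag = 21L, beta_vcov = NULL) {
  n_loc <- length(series_list)
  stopifnot(length(curves) == n_loc, length(mmts) == n_loc,
            length(countries) == n_loc)
  if (n_sim < 100) stop("'n_sim' must be at least 100")
  if (is.null(cutoffs_list))
    cutoffs_list <- lapply(series_list, function(s) range_cutoffs(s$tmean))
  ncomp <- length(attr_components)
  joint <- !is.null(beta_vcov) &&
    all(vapply(curves, function(cu) !is.null(cu$fe_jacobian), TRUE))
  set.seed(stream_seed(seed, 0L))
  if (joint)  # one fixed-effect perturbation per simulation, shared
    Z <- MASS::mvrnorm(n_sim, rep(0, ncol(beta_vcov)), symm(beta_vcov))
  an_sims <- array(0, c(n_loc, ncomp, n_sim))
  deaths <- numeric(n_loc)
  for (i in seq_len(n_loc)) {
    s <- series_list[[i]]
    cu <- curves[[i]]
    check_psd(cu$vcov, "curve vcov")
    ref <- mmts[[i]]$mmt
    B <- exposure_basis(s$tmean, cu$espec)
    Bc <- B - matrix(exposure_basis(ref, cu$espec), nrow(B), ncol(B),
                     byrow = TRUE)
    w <- forward_window_means(s$deaths, lag)
    co <- cutoffs_list[[i]]
    masks <- component_masks(s$tmean, ref,
                             co$temperature[co$percentile == 2.5],
                             co$temperature[co$percentile == 97.5])
    if (joint) {
      k <- length(cu$eta)
      E <- MASS::mvrnorm(n_sim, rep(0, k), symm(cu$cond_vcov))
      if (is.null(dim(E))) E <- matrix(E, nrow = n_sim)
      draws <- matrix(cu$eta, n_sim, k, byrow = TRUE) +
        Z %*% t(cu$fe_jacobian) + E
    } else {
      draws <- MASS::mvrnorm(n_sim, cu$eta, symm(cu$vcov))
      if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_sim)
    }
    anm <- (1 - exp(-(Bc %*% t(draws)))) * w        # days x sims
    an_sims[i, , ] <- t(crossprod(anm, masks))      # comps x sims
    deaths[i] <- sum(s$deaths)
  }
  bounds <- function(an_mat, dtot) {
    # an_mat: comps x sims
    qs <- apply(an_mat, 1, quantile, probs = c(0.025, 0.975), type = 7,
                names = FALSE)
    data.frame(component = attr_components,
               an_low = qs[1, ], an_high = qs[2, ],
               af_low = qs[1, ] / dtot, af_high = qs[2, ] / dtot)
  }
  loc_tabs <- lapply(seq_len(n_loc), function(i)
    cbind(location = if (!is.null(curves[[i]]$location))
      as.character(curves[[i]]$location) else as.character(i),
      bounds(an_sims[i, , , drop = FALSE][1, , ], deaths[i])))
  ctry <- sort(unique(countries))
  ctry_tabs <- lapply(ctry, function(cc) {
    sel <- which(countries == cc)
    m <- apply(an_sims[sel, , , drop = FALSE], c(2, 3), sum)
    cbind(country = cc, bounds(m, sum(deaths[sel])))
  })
  tot <- bounds(apply(an_sims, c(2, 3), sum), sum(deaths))
  list(location = do.call(rbind, loc_tabs),
       country = do.call(rbind, ctry_tabs),
       total = tot, n_sim = n_sim, seed = seed)
}
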
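# End-to-end orchestration: CSV ingestion, the two-stage analysis,
# attribution with empirical confidence intervals, reports and a run
# manifest.

#' Pipeline configuration
#'
#' Collects every analysis setting with defaults reproducing the main
#' model specification: exposure knots at the 10th/75th/90th percentiles
#' of each location's temperatures, a 21-day lag with 3 log-spaced knots,
#' a time spline with 8 df/year, day-of-week indicators, meta-predictors
#' country + average temperature + temperature range, MMT searched over
#' percentiles 1-99, extreme cutoffs at the 2.5th/97.5th percentiles, and
#' 1000 Monte Carlo simulations for the empirical intervals.  Sensitivity
#' analyses are one-setting diffs of this object (alternative knots, df,
#' lag length, attribution perspective).
#'
#' @param data_dir directory of per-location CSVs (`date, deaths, tmean`).
#' @param metadata path to the metadata CSV (`location, country,
#'   avg_tmean, range_tmean`); defaults to `metadata.csv` in `data_dir`.
#' @param out_dir output directory for intermediate files and reports.
#' @param knot_percentiles exposure-spline internal knot percentiles.
#' @param lag maximum lag (days).
#' @param lag_knots number of log-spaced internal lag knots.
#' @param df_per_year time-spline degrees of freedom per year.
#' @param predictors meta-predictor columns (see [meta_design()]).
#' @param mmt_grid integer percentile grid for the MMT search.
#' @param extra_cutoffs additional percentile cutoffs for range tables.
#' @param n_sim Monte Carlo simulations for the empirical intervals.
#' @param seed integer seed for the Monte Carlo draws.
#' @param perspective attribution perspective, `"forward"` or
#'   `"backward"`.
#' @param method meta-regression estimation method, `"reml"` or `"ml"`.
#' @param strict abort on any location fitting failure instead of
#'   excluding the location with a warning.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, metadata = file.path(data_dir, "metadata.csv"),
                            out_dir = tempfile("tempmort_run"),
                            knot_percentiles = c(10, 75, 90), lag = 21L,
                            lag_knots = 3L, df_per_year = 8,
                            predictors = c("country", "avg_tmean", "range_tmean"),
                            mmt_grid = 1:99, extra_cutoffs = numeric(0),
                            n_sim = 1000L, seed = 1L,
                            perspective = c("forward", "backward"),
                            method = c("reml", "ml"), strict = FALSE) {
  perspective <- match.arg(perspective)
  method <- match.arg(method)
  if (any(extra_cutoffs <= 0 | extra_cutoffs >= 100))
    stop("cutoffs must lie strictly in (0, 100)")
  structure(list(data_dir = data_dir, metadata = metadata,
                 out_dir = out_dir, knot_percentiles = knot_percentiles,
                 lag = as.integer(lag), lag_knots = as.integer(lag_knots),
                 df_per_year = df_per_year, predictors = predictors,
                 mmt_grid = mmt_grid, extra_cutoffs = extra_cutoffs,
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 perspective = perspective, method = method,
                 strict = strict),
            class = "pipeline_config")
}

#' Read per-location series and metadata from CSV
#'
#' Loads the metadata table and one CSV per listed location, validating
#' as it goes: parseable ISO dates, non-negative integer death counts,
#' finite temperatures.  Rows are sorted by date (so shuffled input files
#' yield identical output) and calendar gaps are reported as warnings.
#' All validation failures are collected and raised together, itemised by
#' file and row.
#'
#' @param data_dir directory containing `<location>.csv` files.
#' @param metadata path to the metadata CSV.
#' @return list with `series` (named list of data frames) and `metadata`.
#' @export
read_locations <- function(data_dir, metadata = file.path(data_dir, "metadata.csv")) {
  if (!file.exists(metadata)) stop("metadata file not found: ", metadata)
  meta <- read.csv(metadata, stringsAsFactors = FALSE)
  need <- c("location", "country")
  if (!all(need %in% names(meta)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  errors <- character(0)
  series <- list()
  for (loc in meta$location) {
    path <- file.path(data_dir, paste0(loc, ".csv"))
    if (!file.exists(path)) {
      errors <- c(errors, paste0("missing file: ", path))
      next
    }
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("date", "deaths", "tmean") %in% names(df))) {
      errors <- c(errors, paste0(loc, ": needs columns date, deaths, tmean"))
      next
    }
    d <- as.Date(df$date, format = "%Y-%m-%d")
    if (anyNA(d))
      errors <- c(errors, paste0(loc, ": unparseable date at row(s) ",
                                 paste(which(is.na(d)), collapse = ", ")))
    bad <- which(!is.finite(df$deaths) | df$deaths < 0 |
                   df$deaths != round(df$deaths))
    if (length(bad))
      errors <- c(errors, paste0(loc, ": invalid death count at row(s) ",
                                 paste(bad, collapse = ", ")))
    if (any(!is.finite(df$tmean)))
      errors <- c(errors, paste0(loc, ": non-finite temperature at row(s) ",
                                 paste(which(!is.finite(df$tmean)),
                                       collapse = ", ")))
    if (length(errors)) next
    df$date <- d
    df <- df[order(df$date), , drop = FALSE]
    rownames(df) <- NULL
    gaps <- diff(as.numeric(df$date))
    if (any(gaps > 1))
      warning(loc, ": ", sum(gaps > 1), " calendar gap(s) in the series")
    series[[as.character(loc)]] <- df
  }
  if (length(errors))
    stop("input validation failed:\n  ", paste(errors, collapse = "\n  "))
  list(series = series, metadata = meta)
}

# jsonlite-backed serialisation of a meta-analysis fit (resumable state).
save_metafit <- function(fit, path) {
  obj <- list(beta = fit$beta, vcov = fit$vcov, Psi = fit$Psi,
              loglik = fit$loglik, method = fit$method, Q = fit$Q,
              Q_df = fit$Q_df, Q_p = fit$Q_p, I2 = fit$I2, k = fit$k,
              p = fit$p, y = fit$y, S = fit$S, X = fit$X,
              predictors = rownames(fit$beta),
              convergence = fit$convergence)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

load_metafit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- list(beta = matrix(obj$beta, obj$p, obj$k,
                            dimnames = list(obj$predictors, NULL)),
              vcov = matrix(obj$vcov, obj$p * obj$k, obj$p * obj$k),
              Psi = matrix(obj$Psi, obj$k, obj$k), loglik = obj$loglik,
              method = obj$method, Q = obj$Q, Q_df = obj$Q_df,
              Q_p = obj$Q_p, I2 = obj$I2, k = obj$k, p = obj$p,
              y = matrix(obj$y, ncol = obj$k),
              S = lapply(obj$S, function(m) matrix(unlist(m), obj$k, obj$k)),
              X = matrix(obj$X, ncol = obj$p), convergence = obj$convergence)
  class(fit) <- "mvmeta_fit"
  fit
}

# Aggregate per-location component AN tables to country and total level.
aggregate_components <- function(loc_tab, countries, deaths) {
  agg <- function(sel, label, col, val) {
    an <- colSums(loc_tab[sel, attr_components, drop = FALSE])
    d <- sum(deaths[sel])
    out <- data.frame(label, t(an), t(an / d), d)
    names(out) <- c(col, paste0("an_", attr_components),
                    paste0("af_", attr_components), "deaths")
    out
  }
  ctry <- sort(unique(countries))
  country <- do.call(rbind, lapply(ctry, function(cc)
    agg(countries == cc, cc, "country")))
  total <- agg(rep(TRUE, nrow(loc_tab)), "Total", "unit")
  list(country = country, total = total)
}

#' Run the full two-stage pipeline
#'
#' Executes first-stage fits per location, reduction, meta-regression,
#' BLUPs, the MMT search, forward attribution with component splits,
#' Monte Carlo empirical intervals, and report writing.  Intermediate
#' reduced curves and the meta-analysis fit are written to
#' `config$out_dir` and reused on re-runs when present (delete them to
#' force a refit), so attribution settings can be changed without
#' repeating the regression stages.
#'
#' @param config a [pipeline_config()].
#' @return object of class `attribution_result`; see Details.
#' @details The result bundles `point` (per-location, per-country, and
#'   total attributable numbers/fractions by component), `eci` (Monte
#'   Carlo bounds at the same three levels), `mmt` (per-location MMT
#'   results), `metafit`, `blups`, `reports` (paths of written CSVs) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- read_locations(config$data_dir, config$metadata)
  series <- inp$series
  meta <- inp$metadata
  lspec <- lag_basis_spec(config$lag, config$lag_knots)

  # stage 1: location fits + reduction (resumable)
  especs <- lapply(series, function(s)
    exposure_basis_spec(s$tmean, config$knot_percentiles))
  curves_path <- file.path(config$out_dir, "reduced_curves.csv")
  failed <- character(0)
  if (file.exists(curves_path)) {
    message("reusing cached reduced curves: ", curves_path)
    curves <- read_reduced_curves(curves_path, especs)
  } else {
    curves <- list()
    for (loc in names(series)) {
      fit <- tryCatch(
        fit_location(series[[loc]], especs[[loc]], lspec,
                     config$df_per_year),
        error = function(e) e)
      if (inherits(fit, "error")) {
        if (config$strict)
          stop("first stage failed for location ", loc, ": ",
               conditionMessage(fit))
        warning("excluding location ", loc, ": ", conditionMessage(fit))
        failed <- c(failed, loc)
        next
      }
      curves[[loc]] <- reduce_to_overall(fit, lspec, location = loc)
    }
    if (length(curves) == 0) stop("first stage failed for every location")
    write_reduced_curves(curves, curves_path)
  }
  keep <- names(curves)
  series <- series[keep]
  meta <- meta[match(keep, meta$location), , drop = FALSE]

  # stage 2: meta-regression + BLUPs (resumable)
  X <- meta_design(meta, intersect(config$predictors, names(meta)))
  metafit_path <- file.path(config$out_dir, "metafit.json")
  if (file.exists(metafit_path)) {
    message("reusing cached meta-analysis fit: ", metafit_path)
    metafit <- load_metafit(metafit_path)
  } else {
    metafit <- fit_mvmeta(curves, X, method = config$method)
    save_metafit(metafit, metafit_path)
    # work from the serialised representation so that cached re-runs are
    # bit-identical to the first run
    metafit <- load_metafit(metafit_path)
  }
  blups <- compute_blups(metafit, curves, X)

  # stage 3: MMT, attribution, components
  mmts <- lapply(seq_along(blups), function(i)
    find_mmt(blups[[i]], series[[i]]$tmean, config$mmt_grid))
  cutoffs <- lapply(series, function(s)
    range_cutoffs(s$tmean, config$extra_cutoffs))
  loc_rows <- vector("list", length(blups))
  for (i in seq_along(blups)) {
    att <- attributable_forward(series[[i]], blups[[i]], mmts[[i]],
                                lag = config$lag,
                                perspective = config$perspective)
    comp <- split_components(att$an, series[[i]]$tmean, mmts[[i]],
                             cutoffs[[i]], att$deaths_total)
    loc_rows[[i]] <- data.frame(
      location = keep[i], country = meta$country[i],
      deaths = att$deaths_total,
      mmt = mmts[[i]]$mmt, mmt_percentile = mmts[[i]]$mmt_percentile,
      t(unlist(comp[attr_components])))
  }
  loc_tab <- do.call(rbind, loc_rows)
  names(loc_tab)[names(loc_tab) %in% attr_components] <-
    paste0("an_", attr_components)
  for (cc in attr_components)
    loc_tab[[paste0("af_", cc)]] <- loc_tab[[paste0("an_", cc)]] / loc_tab$deaths
  agg <- aggregate_components(
    setNames(loc_tab[paste0("an_", attr_components)], attr_components),
    loc_tab$country, loc_tab$deaths)

  # stage 4: Monte Carlo empirical intervals
  eci <- monte_carlo_eci(series, blups, mmts, meta$country, cutoffs,
                         n_sim = config$n_sim, seed = config$seed,
                         lag = config$lag, beta_vcov = metafit$vcov)

  # stage 5: reports + manifest
  reports <- write_reports(loc_tab, agg, eci, config$out_dir)
  manifest <- write_manifest(config, failed,
                             c(curves_path, metafit_path, unlist(reports)))
  structure(list(point = list(location = loc_tab, country = agg$country,
                              total = agg$total),
                 eci = eci, mmt = mmts, metafit = metafit, blups = blups,
                 cutoffs = cutoffs, series = series, metadata = meta,
                 config = config, reports = reports, manifest = manifest,
                 excluded = failed),
            class = "attribution_result")
}

# Table-2-shaped and Figure-2-shaped CSV reports.
write_reports <- function(loc_tab, agg, eci, out_dir) {
  # country rows + Total: median MMT percentile, total/cold/heat AF + eCI
  ctab <- agg$country
  ctab$mmt_percentile <- vapply(ctab$country, function(cc)
    median(loc_tab$mmt_percentile[loc_tab$country == cc]), 0)
  tot <- agg$total
  tot$mmt_percentile <- median(loc_tab$mmt_percentile)
  eci_pick <- function(tab, unit_col, unit, comp) {
    r <- tab[tab[[unit_col]] == unit & tab$component == comp, ]
    c(low = r$af_low, high = r$af_high)
  }
  mk_row <- function(unit, af_row, tab, unit_col) {
    row <- data.frame(unit = unit, mmt_percentile = af_row$mmt_percentile)
    for (comp in c("total", "cold", "heat")) {
      b <- eci_pick(tab, unit_col, unit, comp)
      row[[paste0("af_", comp)]] <- af_row[[paste0("af_", comp)]]
      row[[paste0("af_", comp, "_low")]] <- b["low"]
      row[[paste0("af_", comp, "_high")]] <- b["high"]
    }
    row
  }
  t2 <- rbind(
    do.call(rbind, lapply(seq_len(nrow(ctab)), function(i)
      mk_row(ctab$country[i], ctab[i, ], eci$country, "country"))),
    mk_row("Total", tot, cbind(unit = "Total", eci$total), "unit"))
  t2_path <- file.path(out_dir, "table_attributable.csv")
  write.csv(t2, t2_path, row.names = FALSE)

  # moderate/extreme x cold/heat per country (+ Total)
  comps <- c("extreme_cold", "moderate_cold", "moderate_heat", "extreme_heat")
  mk_f2 <- function(unit, af_row, tab, unit_col) {
    do.call(rbind, lapply(comps, function(comp) {
      b <- eci_pick(tab, unit_col, unit, comp)
      data.frame(unit = unit, component = comp,
                 af = af_row[[paste0("af_", comp)]],
                 af_low = b["low"], af_high = b["high"])
    }))
  }
  f2 <- rbind(
    do.call(rbind, lapply(seq_len(nrow(ctab)), function(i)
      mk_f2(ctab$country[i], ctab[i, ], eci$country, "country"))),
    mk_f2("Total", tot, cbind(unit = "Total", eci$total), "unit"))
  rownames(f2) <- NULL
  f2_path <- file.path(out_dir, "components_moderate_extreme.csv")
  write.csv(f2, f2_path, row.names = FALSE)
  list(table_attributable = t2_path, components = f2_path)
}

write_manifest <- function(config, excluded, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    package_version = as.character(packageVersion("tempmort")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    excluded_locations = excluded,
    checksums = as.list(tools::md5sum(files)))
  path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

#' Export per-location curve data (and optional plots)
#'
#' Writes one CSV per location with the BLUP overall cumulative
#' exposure-response curve (RR and 95% eCI on a temperature grid centred
#' at the location MMT, where RR = 1 exactly), the MMT, and the
#' extreme-temperature percentile markers.  Optionally draws a simple
#' base-graphics curve per location on the active device.
#'
#' @param result an `attribution_result` from [run_pipeline()].
#' @param dir output directory; defaults to `curves/` under the run
#'   output directory.
#' @param n_grid number of grid points spanning each location's
#'   temperature range.
#' @param plot also draw each curve.
#' @return named list of written file paths, invisibly.
#' @export
export_figures <- function(result, dir = file.path(result$config$out_dir, "curves"),
                           n_grid = 101L, plot = FALSE) {
  stopifnot(inherits(result, "attribution_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (i in seq_along(result$blups)) {
    cu <- result$blups[[i]]
    loc <- as.character(cu$location)
    mmt <- result$mmt[[i]]
    grid <- seq(cu$espec$boundary[1], cu$espec$boundary[2],
                length.out = n_grid)
    grid <- sort(unique(c(grid, mmt$mmt)))
    curve <- predict_curve(cu$eta, cu$vcov, cu$espec, grid, mmt$mmt)
    curve$mmt <- mmt$mmt
    co <- result$cutoffs[[i]]
    curve$p_low <- co$temperature[co$percentile == 2.5]
    curve$p_high <- co$temperature[co$percentile == 97.5]
    path <- file.path(dir, paste0(loc, "_curve.csv"))
    write.csv(curve, path, row.names = FALSE)
    paths[[loc]] <- path
    if (plot) {
      plot(curve$temperature, curve$rr, type = "l", lwd = 2,
           xlab = "Temperature (°C)", ylab = "RR", main = loc)
      graphics::polygon(c(curve$temperature, rev(curve$temperature)),
                        c(curve$rr_low, rev(curve$rr_high)),
                        col = grDevices::grey(0.85), border = NA)
      graphics::lines(curve$temperature, curve$rr, lwd = 2)
      graphics::abline(v = mmt$mmt, col = "grey40")
      graphics::abline(v = c(curve$p_low[1], curve$p_high[1]),
                       col = "grey40", lty = 2)
    }
  }
  invisible(paths)
}

#' Read a country-level metadata summary table
#'
#' Reads a descriptive table with one row per country: number of
#' locations, study period, total deaths, and the mean location-specific
#' temperature with its range.  A packaged example shaped like the
#' descriptive table of a 13-country, 384-location mortality dataset is
#' available via
#' `system.file("extdata", "country-metadata.csv", package = "tempmort")`.
#'
#' @param path CSV with columns `country, locations, period_start,
#'   period_end, total_deaths, avg_tmean, tmean_low, tmean_high`.
#' @return data frame with those columns plus a `grand_total_deaths`
#'   attribute (the sum of the country totals).
#' @export
read_country_metadata <- function(path = system.file("extdata", "country-metadata.csv",
                                                     package = "tempmort")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "locations", "total_deaths")
  if (!all(need %in% names(df)))
    stop("country metadata must contain: ", paste(need, collapse = ", "))
  attr(df, "grand_total_deaths") <- sum(df$total_deaths)
  df
}
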
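# First stage: location-specific quasi-Poisson regression with a DLNM
# term, and reduction to the overall cumulative exposure-response curve.

#' Natural cubic spline of time for seasonal and long-term trend control
#'
#' Spline of the day index with `round(df_per_year * n_days / 365.25)`
#' total degrees of freedom and knots at equally spaced quantiles of the
#' index (no intercept; the regression supplies its own).
#'
#' @param dates sorted vector of daily dates (`Date` or integer day index).
#' @param df_per_year degrees of freedom per year (default 8).
#' @return matrix with one column per degree of freedom.
#' @export
build_time_spline <- function(dates, df_per_year = 8) {
  n <- length(dates)
  if (n < 2 || is.unsorted(as.numeric(dates)))
    stop("'dates' must be a sorted daily sequence")
  df <- round(df_per_year * n / 365.25)
  if (df < 2) stop("total time-spline df must be at least 2")
  b <- splines::ns(seq_len(n), df = df)
  m <- matrix(as.numeric(b), nrow = n)
  colnames(m) <- paste0("time", seq_len(ncol(m)))
  m
}

#' Day-of-week indicator matrix
#'
#' Reference-coded weekday indicators (Monday is the reference), six
#' columns.
#'
#' @param dates vector of `Date` values.
#' @return matrix of 0/1 indicators with columns `dowTue` ... `dowSun`.
#' @export
build_dow <- function(dates) {
  wd <- as.integer(format(as.Date(dates), "%u"))   # 1 = Monday ... 7 = Sunday
  lab <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  m <- sapply(2:7, function(k) as.numeric(wd == k))
  m <- matrix(m, nrow = length(dates))
  colnames(m) <- paste0("dow", lab[2:7])
  m
}

#' Quasi-Poisson regression by iteratively reweighted least squares
#'
#' Log-link Poisson IRLS run to convergence (relative deviance change
#' below `1e-9`, at most 50 iterations), with the dispersion estimated
#' from the Pearson statistic: `phi = sum(pearson^2) / (n - p)` and
#' coefficient covariance `phi * (X'WX)^{-1}`.
#'
#' @param y non-negative integer counts.
#' @param X design matrix including the intercept; must have full column
#'   rank.
#' @param col_map optional named list of column index vectors identifying
#'   design blocks (kept on the fit for downstream reduction).
#' @return object of class `first_stage_fit` with elements `coefficients`,
#'   `vcov`, `dispersion`, `df_residual`, `fitted`, `col_map`.
#' @export
fit_quasipoisson <- function(y, X, col_map = NULL) {
  X <- as.matrix(X)
  if (any(y < 0) || any(y != round(y))) stop("'y' must be non-negative integer counts")
  if (nrow(X) != length(y)) stop("dimension mismatch between 'y' and 'X'")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::glm.fit(X, y, family = poisson(),
                        control = list(epsilon = 1e-9, maxit = 50))
  if (!fit$converged)
    stop("IRLS did not converge in 50 iterations (deviance ",
         format(fit$deviance), ")")
  mu <- fit$fitted.values
  p <- ncol(X)
  n <- length(y)
  phi <- sum((y - mu)^2 / mu) / (n - p)
  XtWX <- crossprod(X * sqrt(mu))
  vcov <- phi * chol2inv(chol(XtWX))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = setNames(fit$coefficients, colnames(X)),
                 vcov = vcov, dispersion = phi, df_residual = n - p,
                 fitted = mu, deviance = fit$deviance, col_map = col_map),
            class = "first_stage_fit")
}

#' Fit the first-stage model for one location
#'
#' Assembles the design (intercept, time spline with `df_per_year`
#' degrees of freedom per year, day-of-week indicators, DLNM cross-basis)
#' and fits the quasi-Poisson regression.  Days with missing deaths or
#' temperature are dropped from the likelihood with a warning (the
#' cross-basis is built on the full temperature series first, so lagged
#' exposure history is preserved for retained days).
#'
#' @param series data frame with columns `date`, `deaths`, `tmean`.
#' @param espec exposure basis specification; derived from the location's
#'   temperatures when `NULL`.
#' @param lspec lag basis specification.
#' @param df_per_year time-spline degrees of freedom per year.
#' @return `first_stage_fit` with the cross-basis specs attached.
#' @export
fit_location <- function(series, espec = NULL, lspec = lag_basis_spec(),
                         df_per_year = 8) {
  stopifnot(all(c("date", "deaths", "tmean") %in% names(series)))
  keep <- is.finite(series$tmean) & is.finite(series$deaths)
  if (!all(keep)) {
    warning(sum(!keep), " day(s) with missing deaths or temperature dropped")
    series <- series[keep, , drop = FALSE]
  }
  if (is.null(espec)) espec <- exposure_basis_spec(series$tmean)
  cb <- build_crossbasis(series$tmean, espec, lspec)
  ts <- build_time_spline(series$date, df_per_year)
  dow <- build_dow(series$date)
  X <- cbind(`(Intercept)` = 1, ts, dow, cb)
  ncb <- ncol(cb)
  colnames(X)[(ncol(X) - ncb + 1):ncol(X)] <-
    paste0("cb", rep(seq_len(espec$vx), each = lspec$vl), ".",
           rep(seq_len(lspec$vl), espec$vx))
  col_map <- list(intercept = 1L,
                  time = 1L + seq_len(ncol(ts)),
                  dow = 1L + ncol(ts) + seq_len(ncol(dow)),
                  crossbasis = 1L + ncol(ts) + ncol(dow) + seq_len(ncb))
  fit <- fit_quasipoisson(series$deaths, X, col_map = col_map)
  fit$espec <- espec
  fit$lspec <- lspec
  fit
}

#' Reduce a first-stage fit to the overall cumulative curve
#'
#' Cumulates the fitted risk surface over the integer lag grid
#' `l = 0..L`: with `c_k = sum_l C_k(l)`, the reduced coefficients are
#' `eta = (I_vx  %x%  c') theta_cb` and the covariance transforms by the
#' same linear map.  The resulting vx-dimensional curve (coefficients plus
#' covariance) is the quantity pooled in the second stage.
#'
#' @param fit a `first_stage_fit` containing a cross-basis block.
#' @param lspec lag basis specification consistent with the fit; defaults
#'   to the one stored on the fit.
#' @param location optional location identifier carried on the result.
#' @return object of class `reduced_curve` with elements `eta`, `vcov`,
#'   `espec`, `location`.
#' @export
reduce_to_overall <- function(fit, lspec = fit$lspec, location = NA) {
  stopifnot(inherits(fit, "first_stage_fit"))
  idx <- fit$col_map$crossbasis
  if (is.null(idx)) stop("fit has no cross-basis block")
  cvec <- colSums(lag_basis(lspec))
  vl <- length(cvec)
  if (length(idx) %% vl != 0)
    stop("cross-basis block size ", length(idx),
         " is not a multiple of the lag-basis dimension ", vl)
  vx <- length(idx) %/% vl
  M <- kronecker(diag(vx), t(cvec))
  theta <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  structure(list(eta = drop(M %*% theta), vcov = symm(M %*% V %*% t(M)),
                 espec = fit$espec, location = location),
            class = "reduced_curve")
}

#' Serialise reduced curves to a flat CSV
#'
#' One row per location: `location, eta_1..eta_vx`, then the
#' lower-triangle of the covariance in row-major order (`v_1_1, v_2_1,
#' v_2_2, ...`).  Round-trips through [read_reduced_curves()] given the
#' shared exposure specs.
#'
#' @param curves list of `reduced_curve` objects.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_reduced_curves <- function(curves, path) {
  vx <- length(curves[[1]]$eta)
  lt <- which(lower.tri(diag(vx), diag = TRUE), arr.ind = TRUE)
  rows <- lapply(curves, function(cu) {
    c(setNames(cu$eta, paste0("eta_", seq_len(vx))),
      setNames(cu$vcov[lt], paste0("v_", lt[, 1], "_", lt[, 2])))
  })
  df <- cbind(data.frame(location = vapply(curves, function(cu)
    as.character(cu$location), character(1))), do.call(rbind, rows))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read reduced curves back from CSV
#'
#' @param path CSV written by [write_reduced_curves()].
#' @param especs optional named list of exposure specs (by location) to
#'   re-attach.
#' @return list of `reduced_curve` objects.
#' @export
read_reduced_curves <- function(path, especs = NULL) {
  df <- read.csv(path, check.names = FALSE)
  eta_cols <- grep("^eta_", names(df))
  vx <- length(eta_cols)
  lt <- which(lower.tri(diag(vx), diag = TRUE), arr.ind = TRUE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    V <- matrix(0, vx, vx)
    V[lt] <- as.numeric(df[i, grep("^v_", names(df))])
    V <- V + t(V) - diag(diag(V))
    loc <- df$location[i]
    structure(list(eta = as.numeric(df[i, eta_cols]), vcov = V,
                   espec = especs[[as.character(loc)]], location = loc),
              class = "reduced_curve")
  })
  names(out) <- as.character(df$location)
  out
}
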
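# Spline bases and the exposure x lag cross-basis of the DLNM.

#' B-spline basis with polynomial extension beyond the boundary
#'
#' Evaluates a B-spline basis by the Cox-de Boor construction
#' (via [splines::splineDesign()]).  Points outside the boundary knots are
#' evaluated by extending the boundary polynomial pieces (a Taylor
#' expansion of the basis at the nearer boundary), so the basis is defined
#' on the whole real line.  With `intercept = TRUE` the full basis is
#' returned and rows sum to one inside the boundary (partition of unity);
#' with `intercept = FALSE` the first column is dropped.
#'
#' @param x numeric vector of evaluation points; `NA`/`NaN` are an error.
#' @param degree polynomial degree (0 = piecewise constant, 2 = quadratic).
#' @param internal_knots numeric vector of internal knots, strictly inside
#'   `boundary`; may be empty.
#' @param boundary length-2 numeric, the boundary knots.
#' @param intercept keep the full basis (`TRUE`) or drop its first column.
#' @return numeric matrix, `length(x)` rows and
#'   `degree + length(internal_knots) + intercept` columns, with attribute
#'   `outside` flagging extrapolated rows.
#' @export
bspline_basis <- function(x, degree = 2, internal_knots = numeric(0),
                          boundary = range(x), intercept = FALSE) {
  if (anyNA(x)) stop("NA/NaN in 'x' is not allowed")
  if (degree < 0) stop("'degree' must be >= 0")
  boundary <- sort(as.numeric(boundary))
  internal_knots <- as.numeric(sort(internal_knots))
  if (length(internal_knots) &&
      (any(internal_knots <= boundary[1]) || any(internal_knots >= boundary[2])))
    stop("internal knots must lie strictly inside the boundary")
  ord <- degree + 1L
  aknots <- c(rep(boundary[1], ord), internal_knots, rep(boundary[2], ord))
  ncol_full <- length(internal_knots) + ord
  res <- matrix(0, length(x), ncol_full)
  outside <- x < boundary[1] | x > boundary[2]
  if (any(!outside))
    res[!outside, ] <- splines::splineDesign(aknots, x[!outside], ord = ord)
  if (any(outside)) {
    # Taylor expansion of the basis at the nearer boundary, as splines::bs()
    scalef <- gamma(seq_len(ord))          # 0!, 1!, ..., degree!
    for (side in c(1L, 2L)) {
      sel <- if (side == 1L) x < boundary[1] else x > boundary[2]
      if (!any(sel)) next
      piv <- boundary[side]
      tt <- splines::splineDesign(aknots, rep(piv, ord), ord = ord,
                                  derivs = 0:(ord - 1L))
      xl <- cbind(1, outer(x[sel] - piv, seq_len(degree), `^`))[, seq_len(ord), drop = FALSE]
      res[sel, ] <- xl %*% (tt / scalef)
    }
  }
  if (!intercept) res <- res[, -1L, drop = FALSE]
  attr(res, "outside") <- outside
  res
}

#' Natural cubic spline basis
#'
#' Cubic spline basis constrained to be linear beyond the boundary knots
#' (zero second derivative at and outside the boundaries), built on
#' [splines::ns()].  Dimension is `length(internal_knots) + 1` plus one if
#' `intercept = TRUE`.
#'
#' @param x numeric vector of evaluation points.
#' @param internal_knots strictly increasing knots inside the boundary.
#' @param boundary length-2 numeric boundary knots.
#' @param intercept include an intercept column in the basis.
#' @return numeric matrix (plain, without the `ns` class).
#' @export
natural_cubic_basis <- function(x, internal_knots = numeric(0),
                                boundary = range(x), intercept = FALSE) {
  if (anyNA(x)) stop("NA/NaN in 'x' is not allowed")
  internal_knots <- as.numeric(internal_knots)
  if (anyDuplicated(internal_knots)) stop("duplicate internal knots")
  if (is.unsorted(internal_knots)) stop("internal knots must be increasing")
  b <- splines::ns(x, knots = internal_knots, Boundary.knots = sort(boundary),
                   intercept = intercept)
  m <- matrix(as.numeric(b), nrow = length(x))
  dimnames(m) <- NULL
  m
}

#' Lag knots equally spaced on the log scale
#'
#' Internal knots for the lag-response spline: the `n_knots` interior
#' points of an equally spaced grid from `log(1)` to `log(L)` with
#' `n_knots + 2` points, exponentiated back to the lag scale.
#'
#' @param L maximum lag (days), at least 2.
#' @param n_knots number of internal knots, at least 1 and less than `L`.
#' @return numeric vector of knots in `(1, L)`.
#' @export
log_lag_knots <- function(L = 21L, n_knots = 3L) {
  if (L < 2) stop("'L' must be >= 2")
  if (n_knots < 1) stop("'n_knots' must be >= 1")
  if (n_knots >= L) stop("'n_knots' must be smaller than 'L'")
  grid <- seq(log(1), log(L), length.out = n_knots + 2L)
  exp(grid[-c(1L, n_knots + 2L)])
}

#' Exposure basis specification
#'
#' Records the quadratic B-spline used for the exposure-response
#' dimension: internal knots at given percentiles of the location's
#' temperature distribution (defaults 10th, 75th and 90th), boundary knots
#' at the observed minimum and maximum, no intercept.  Empirical quantiles
#' use the linear-interpolation (type 7) convention.
#'
#' @param temps the location's daily mean temperatures (degrees C).
#' @param knot_percentiles percentiles (0-100 scale) for the internal knots.
#' @param degree spline degree; the default quadratic gives dimension
#'   `degree + length(knot_percentiles)` = 5.
#' @return object of class `exposure_basis_spec`.
#' @export
exposure_basis_spec <- function(temps, knot_percentiles = c(10, 75, 90),
                                degree = 2L) {
  temps <- temps[is.finite(temps)]
  if (!length(temps)) stop("no finite temperatures")
  knots <- quantile(temps, knot_percentiles / 100, type = 7, names = FALSE)
  boundary <- range(temps)
  if (any(knots <= boundary[1]) || any(knots >= boundary[2]) ||
      any(diff(knots) <= 0))
    stop("degenerate temperature distribution: knots not strictly increasing inside the boundary")
  structure(list(degree = as.integer(degree), knots = knots,
                 boundary = boundary, knot_percentiles = knot_percentiles,
                 vx = as.integer(degree + length(knots))),
            class = "exposure_basis_spec")
}

#' Lag basis specification
#'
#' Natural cubic spline over the lag range `[0, L]` with an intercept and
#' internal knots equally spaced on the log-lag scale; the defaults
#' (L = 21, 3 knots) give dimension 5.
#'
#' @param L maximum lag in days.
#' @param n_knots number of internal knots on the log scale.
#' @return object of class `lag_basis_spec`.
#' @export
lag_basis_spec <- function(L = 21L, n_knots = 3L) {
  knots <- log_lag_knots(L, n_knots)
  structure(list(L = as.integer(L), knots = knots, boundary = c(0, L),
                 intercept = TRUE, vl = as.integer(n_knots + 2L)),
            class = "lag_basis_spec")
}

#' Evaluate the exposure basis of a specification
#'
#' @param x temperatures at which to evaluate.
#' @param espec an [exposure_basis_spec()].
#' @return matrix with `espec$vx` columns.
#' @export
exposure_basis <- function(x, espec) {
  stopifnot(inherits(espec, "exposure_basis_spec"))
  bspline_basis(x, degree = espec$degree, internal_knots = espec$knots,
                boundary = espec$boundary, intercept = FALSE)
}

#' Evaluate the lag basis on the integer lag grid
#'
#' @param lspec a [lag_basis_spec()].
#' @param at lag values; defaults to the integer grid `0:L`.
#' @return matrix with `lspec$vl` columns.
#' @export
lag_basis <- function(lspec, at = 0:lspec$L) {
  stopifnot(inherits(lspec, "lag_basis_spec"))
  natural_cubic_basis(at, internal_knots = lspec$knots,
                      boundary = lspec$boundary, intercept = lspec$intercept)
}

#' Build the DLNM cross-basis
#'
#' Tensor-product design of the exposure basis R and lag basis C:
#' entry `(t, (j-1)*vl + k)` equals `sum_l R_j(x[t-l]) * C_k(l)` over the
#' integer lags `l = 0..L` (exposure-major column ordering).  Rows with
#' fewer than `L` days of history use the available history only
#' (truncated sums) and are flagged as edge rows.
#'
#' @param temps daily mean temperature vector, longer than `lspec$L`.
#' @param espec exposure basis specification; computed from `temps` when
#'   `NULL`.
#' @param lspec lag basis specification.
#' @return matrix of class `crossbasis` with attributes `espec`, `lspec`
#'   and `edge` (logical row flags).
#' @export
build_crossbasis <- function(temps, espec = NULL, lspec = lag_basis_spec()) {
  if (anyNA(temps) || any(!is.finite(temps)))
    stop("missing/non-finite temperatures at positions: ",
         paste(which(!is.finite(temps)), collapse = ", "))
  if (is.null(espec)) espec <- exposure_basis_spec(temps)
  L <- lspec$L
  n <- length(temps)
  if (n <= L) stop("series must be longer than the lag period")
  R <- exposure_basis(temps, espec)
  C <- lag_basis(lspec)
  vx <- ncol(R); vl <- ncol(C)
  cb <- matrix(0, n, vx * vl)
  jj <- rep(seq_len(vx), each = vl)     # exposure index per column
  kk <- rep(seq_len(vl), times = vx)    # lag index per column
  for (l in 0:L) {
    rows <- (l + 1):n
    # contribution of lag l: R_j(x[t-l]) * C_k(l)
    cb[rows, ] <- cb[rows, ] +
      R[rows - l, jj, drop = FALSE] *
      matrix(C[l + 1, kk], length(rows), vx * vl, byrow = TRUE)
  }
  structure(cb, espec = espec, lspec = lspec,
            edge = seq_len(n) <= L, class = c("crossbasis", "matrix"))
}

#' Predict an overall cumulative exposure-response curve
#'
#' Computes the log relative risk `[R(x) - R(ref)]' coefs` on a
#' temperature grid, with pointwise variance from the same contrast
#' applied to `vcov`, and normal-approximation 95% intervals.  RR at the
#' reference is exactly 1.
#'
#' @param coefs reduced coefficient vector (length `espec$vx`).
#' @param vcov coefficient covariance matrix (positive semidefinite).
#' @param espec exposure basis specification.
#' @param at temperature grid.
#' @param ref reference temperature (typically the minimum-mortality
#'   temperature).
#' @param level confidence level for the pointwise interval.
#' @return data frame with columns `temperature`, `logrr`, `se`, `rr`,
#'   `rr_low`, `rr_high`.
#' @export
predict_curve <- function(coefs, vcov, espec, at, ref, level = 0.95) {
  stopifnot(length(coefs) == espec$vx)
  vcov <- as.matrix(vcov)
  check_psd(vcov, "vcov")
  Z <- exposure_basis(at, espec) -
    matrix(exposure_basis(ref, espec), length(at), espec$vx, byrow = TRUE)
  logrr <- drop(Z %*% coefs)
  se <- sqrt(pmax(rowSums((Z %*% vcov) * Z), 0))
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(temperature = at, logrr = logrr, se = se,
             rr = exp(logrr), rr_low = exp(logrr - z * se),
             rr_high = exp(logrr + z * se))
}

#' Write a predicted curve to CSV
#'
#' Plain-text export with columns `temperature, logrr, rr, rr_low,
#' rr_high`, the dialect consumed by the reporting utilities.
#'
#' @param curve data frame from [predict_curve()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(curve[, c("temperature", "logrr", "rr", "rr_low", "rr_high")],
            path, row.names = FALSE)
  invisible(path)
}
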
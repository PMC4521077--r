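# Second stage: multivariate random-effects meta-regression of the
# reduced curves, heterogeneity statistics, and best linear unbiased
# predictions.
#
# Model: eta_hat_i ~ N((x_i' %x% I_k) beta, S_i + Psi), with S_i the
# within-location covariance from the first stage and Psi the
# between-location covariance, estimated by (RE)ML.  beta is stored
# predictor-major: beta_vec = (beta[pred 1, dims 1..k], beta[pred 2, ...]).

#' Meta-regression design matrix
#'
#' Builds the per-location fixed-effect design: an intercept, optional
#' reference-coded country indicators (reference = first country
#' alphabetically), and optional numeric meta-predictors such as the
#' location average temperature and temperature range.
#'
#' @param metadata data frame with one row per location; must contain a
#'   `location` column plus any requested predictor columns.
#' @param predictors character vector naming metadata columns to include;
#'   a `country` column (factor/character) is expanded to indicators.
#' @return numeric matrix with one row per location (rownames =
#'   locations) and an `(Intercept)` first column.
#' @export
meta_design <- function(metadata,
                        predictors = c("country", "avg_tmean", "range_tmean")) {
  stopifnot("location" %in% names(metadata))
  n <- nrow(metadata)
  X <- matrix(1, n, 1, dimnames = list(metadata$location, "(Intercept)"))
  for (pr in predictors) {
    if (!pr %in% names(metadata))
      stop("metadata has no column '", pr, "'")
    v <- metadata[[pr]]
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) > 1) {
        ind <- sapply(lev[-1], function(l) as.numeric(v == l))
        ind <- matrix(ind, nrow = n,
                      dimnames = list(NULL, paste0(pr, lev[-1])))
        X <- cbind(X, ind)
      }
    } else {
      X <- cbind(X, matrix(as.numeric(v), n, 1, dimnames = list(NULL, pr)))
    }
  }
  if (qr(X)$rank < ncol(X)) stop("meta-regression design is rank deficient")
  X
}

# Lower-triangular Cholesky factor from an unconstrained parameter vector
# (log-diagonal), and its inverse mapping.
chol_from_par <- function(par, k) {
  L <- matrix(0, k, k)
  diag(L) <- exp(par[seq_len(k)])
  if (k > 1) L[lower.tri(L)] <- par[-seq_len(k)]
  L
}

par_from_psi <- function(Psi, k) {
  ev <- eigen(symm(Psi), symmetric = TRUE)
  lam <- pmax(ev$values, 1e-8 * max(ev$values, 1e-8))
  L <- t(chol(symm(ev$vectors %*% (lam * t(ev$vectors)))))
  c(log(pmax(diag(L), 1e-10)), L[lower.tri(L)])
}

# Profile negative log-likelihood (without additive constants) and the
# GLS quantities at a given Psi.
mvmeta_profile <- function(Psi, y, S, X, reml = TRUE) {
  n <- nrow(y); k <- ncol(y); p <- ncol(X)
  pk <- p * k
  U <- matrix(0, pk, pk)
  v <- numeric(pk)
  W <- vector("list", n)
  ld <- 0
  for (i in seq_len(n)) {
    Sig <- S[[i]] + Psi
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(list(nll = 1e10))
    ld <- ld + 2 * sum(log(diag(ch)))
    Wi <- chol2inv(ch)
    W[[i]] <- Wi
    xx <- tcrossprod(X[i, ])
    U <- U + kronecker(xx, Wi)
    v <- v + kronecker(X[i, ], Wi %*% y[i, ])
  }
  chU <- tryCatch(chol(U), error = function(e) NULL)
  if (is.null(chU)) return(list(nll = 1e10))
  beta <- drop(chol2inv(chU) %*% v)
  rss <- 0
  for (i in seq_len(n)) {
    r <- y[i, ] - drop(matrix(beta, k, p) %*% X[i, ])
    rss <- rss + drop(crossprod(r, W[[i]] %*% r))
  }
  nll <- 0.5 * (ld + rss)
  if (reml) nll <- nll + sum(log(diag(chU)))
  list(nll = nll, beta = beta, vcov = chol2inv(chU), W = W)
}

#' Fit a multivariate random-effects meta-regression
#'
#' Pools vx-dimensional reduced curves across locations under the model
#' `eta_i ~ N((x_i' %x% I) beta, S_i + Psi)`.  `Psi` is estimated by
#' restricted maximum likelihood (default) or maximum likelihood,
#' profiling out `beta`; the optimiser works on a Cholesky
#' parameterisation of `Psi` (log-diagonal), which enforces positive
#' semidefiniteness without constraints, using BFGS with deterministic
#' perturbed restarts on non-convergence.  Non-intercept meta-predictors
#' are centred and scaled internally for conditioning; estimates are
#' returned on the original scale.
#'
#' @param curves list of `reduced_curve` (or `blup_curve`) objects with
#'   elements `eta` and `vcov`.
#' @param X fixed-effects design matrix, one row per curve (see
#'   [meta_design()]); defaults to intercept only.
#' @param method `"reml"` (default) or `"ml"`.
#' @return object of class `mvmeta_fit` with elements `beta` (p x k
#'   matrix), `vcov` (pk x pk, predictor-major), `Psi`, `loglik`,
#'   `method`, `Q`, `Q_df`, `Q_p`, `I2`, `convergence`, plus the inputs
#'   (`y`, `S`, `X`) for downstream prediction.
#' @export
fit_mvmeta <- function(curves, X = NULL, method = c("reml", "ml")) {
  method <- match.arg(method)
  n <- length(curves)
  y <- do.call(rbind, lapply(curves, function(cu) cu$eta))
  S <- lapply(curves, function(cu) {
    V <- symm(as.matrix(cu$vcov))
    check_psd(V, "curve vcov")
    V
  })
  k <- ncol(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  p <- ncol(X)
  if (n <= p)
    stop("need more locations (", n, ") than fixed-effect predictors (", p, ")")

  # centre/scale non-constant columns for optimisation conditioning
  const <- apply(X, 2, function(c) diff(range(c)) == 0)
  ctr <- ifelse(const, 0, colMeans(X))
  scl <- ifelse(const, 1, apply(X, 2, sd))
  scl[scl == 0 | !is.finite(scl)] <- 1
  if (!any(const)) ctr[] <- 0   # no intercept to absorb centring
  Xs <- sweep(sweep(X, 2, ctr, `-`), 2, scl, `/`)

  reml <- method == "reml"
  # starting Psi: moment estimate from fixed-effect residuals
  fe <- mvmeta_profile(matrix(0, k, k), y, S, Xs, reml = FALSE)
  res <- y - Xs %*% t(matrix(fe$beta, k, p))
  Smean <- Reduce(`+`, S) / n
  Psi0 <- symm(crossprod(res) / max(n - p, 1) - Smean)
  ev <- eigen(Psi0, symmetric = TRUE)
  Psi0 <- symm(ev$vectors %*% (pmax(ev$values, 0.01 * mean(diag(Smean))) *
                                 t(ev$vectors)))
  par0 <- par_from_psi(Psi0, k)

  obj <- function(par) mvmeta_profile(tcrossprod(chol_from_par(par, k)),
                                      y, S, Xs, reml = reml)$nll
  best <- NULL
  for (attempt in 0:5) {
    start <- if (attempt == 0) par0 else
      par0 + (-1)^attempt * 0.3 * attempt * seq_along(par0) / length(par0)
    opt <- tryCatch(
      optim(start, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
    if (best$convergence == 0 && attempt >= 0) break
  }
  if (is.null(best)) stop("meta-regression optimisation failed")
  Psi <- symm(tcrossprod(chol_from_par(best$par, k)))
  prof <- mvmeta_profile(Psi, y, S, Xs, reml = reml)

  # back-transform beta to the original predictor scale:
  # per outcome dimension beta = A beta_s with A undoing centring/scaling
  A <- diag(1 / scl, p, p)
  icol <- which(const)[1]
  if (!is.na(icol)) A[icol, ] <- A[icol, ] - ctr / scl * (seq_len(p) != icol)
  Ak <- kronecker(A, diag(k))
  beta_vec <- drop(Ak %*% prof$beta)
  vcov <- symm(Ak %*% prof$vcov %*% t(Ak))
  beta <- t(matrix(beta_vec, k, p))
  rownames(beta) <- colnames(X)
  colnames(beta) <- paste0("eta_", seq_len(k))
  cn <- paste0(rep(colnames(X), each = k), ":", rep(seq_len(k), p))
  dimnames(vcov) <- list(cn, cn)

  const_ll <- -0.5 * (n * k - if (reml) p * k else 0) * log(2 * pi)
  het <- cochran_q_i2(curves, X)
  structure(list(beta = beta, vcov = vcov, Psi = Psi,
                 loglik = -best$value + const_ll, method = method,
                 Q = het$Q, Q_df = het$df, Q_p = het$p, I2 = het$I2,
                 convergence = best$convergence, k = k, p = p,
                 y = y, S = S, X = X),
            class = "mvmeta_fit")
}

#' @export
print.mvmeta_fit <- function(x, ...) {
  cat("Multivariate meta-regression (", toupper(x$method), ")\n", sep = "")
  cat("Locations:", nrow(x$y), "  outcome dim:", x$k,
      "  predictors:", x$p, "\n")
  cat("logLik:", format(x$loglik, digits = 6), "\n")
  cat("Cochran Q =", format(x$Q, digits = 5), "on", x$Q_df,
      "df (p =", format.pval(x$Q_p), "),  I2 =",
      sprintf("%.1f%%", x$I2), "\n")
  invisible(x)
}

#' Multivariate Wald test of meta-regression coefficients
#'
#' Tests whether a block of fixed-effect coefficients is zero:
#' `W = b' V_b^{-1} b ~ chi-square(|b|)` under the null.  The block is
#' selected either by predictor name (all k outcome dimensions of those
#' predictors) or by direct indices into the vectorised coefficients.
#'
#' @param fit an `mvmeta_fit`.
#' @param predictors character vector of predictor (row) names of
#'   `fit$beta`; country indicator groups can be selected by prefix.
#' @param index alternatively, integer indices into the vectorised
#'   (predictor-major) coefficient vector.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
wald_test <- function(fit, predictors = NULL, index = NULL) {
  stopifnot(inherits(fit, "mvmeta_fit"))
  k <- fit$k
  if (is.null(index)) {
    if (is.null(predictors)) stop("give 'predictors' or 'index'")
    rows <- unlist(lapply(predictors, function(pr) {
      hit <- which(rownames(fit$beta) == pr)
      if (!length(hit)) hit <- grep(paste0("^", pr), rownames(fit$beta))
      if (!length(hit)) stop("no predictor matching '", pr, "'")
      hit
    }))
    index <- as.vector(outer(seq_len(k), (unique(rows) - 1) * k, `+`))
  }
  if (!length(index) || any(index < 1 | index > length(fit$beta)))
    stop("invalid coefficient subset")
  b <- as.vector(t(fit$beta))[index]
  V <- fit$vcov[index, index, drop = FALSE]
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular covariance block in Wald test"))
  W <- drop(crossprod(backsolve(ch, b, transpose = TRUE)))
  list(statistic = W, df = length(index),
       p_value = pchisq(W, length(index), lower.tail = FALSE))
}

#' Multivariate Cochran Q and I-squared heterogeneity statistics
#'
#' `Q` is the generalised residual weighted sum of squares about the
#' fixed-effects (Psi = 0) GLS fit; `I2 = max(0, (Q - df)/Q) * 100`
#' summarises the share of total variation due to between-location
#' heterogeneity.
#'
#' @param curves list of `reduced_curve` objects.
#' @param X fixed-effects design matrix (default intercept only).
#' @return list with `Q`, `df`, `p`, `I2`.
#' @export
cochran_q_i2 <- function(curves, X = NULL) {
  n <- length(curves)
  y <- do.call(rbind, lapply(curves, function(cu) cu$eta))
  k <- ncol(y)
  S <- lapply(curves, function(cu) symm(as.matrix(cu$vcov)))
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  fe <- mvmeta_profile(matrix(0, k, k), y, S, X, reml = FALSE)
  if (is.null(fe$beta)) stop("singular within-location covariance")
  B <- t(matrix(fe$beta, k, p))
  Q <- 0
  for (i in seq_len(n)) {
    r <- y[i, ] - drop(crossprod(B, X[i, ]))
    Q <- Q + drop(crossprod(r, fe$W[[i]] %*% r))
  }
  df <- n * k - p * k
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE),
       I2 = max(0, (Q - df) / Q) * 100)
}

#' Best linear unbiased predictions of location curves
#'
#' Shrinks each location's reduced curve towards its fixed-effect
#' prediction:
#' `eta_blup_i = X_i beta + Psi (S_i + Psi)^{-1} (eta_i - X_i beta)`,
#' with covariance `Psi - Psi (S_i+Psi)^{-1} Psi + A_i V_beta A_i'` where
#' `A_i = (I - Psi (S_i+Psi)^{-1}) (x_i' %x% I)` accounts for the
#' estimated fixed effects.  As `S_i -> 0` the BLUP tends to the location
#' estimate; as `Psi -> 0` it tends to the fixed-effect prediction.
#'
#' @param fit an `mvmeta_fit`.
#' @param curves list of `reduced_curve` objects; defaults to those used
#'   in the fit (exposure specs are taken from here).
#' @param X design matrix; defaults to the one used in the fit.
#' @return list of `blup_curve` objects (same contract as
#'   `reduced_curve`, with `blup = TRUE`).
#' @export
compute_blups <- function(fit, curves = NULL, X = fit$X) {
  stopifnot(inherits(fit, "mvmeta_fit"))
  k <- fit$k; p <- fit$p
  y <- fit$y; S <- fit$S
  n <- nrow(y)
  Psi <- fit$Psi
  out <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- X[i, ]
    mu <- drop(crossprod(fit$beta, xi))
    Sig <- S[[i]] + Psi
    ch <- tryCatch(chol(Sig), error = function(e)
      stop("singular S_i + Psi for location ", i))
    Wi <- chol2inv(ch)
    G <- Psi %*% Wi                         # shrinkage weight on the data
    eta <- mu + drop(G %*% (y[i, ] - mu))
    Xi <- kronecker(t(xi), diag(k))         # k x pk, predictor-major
    Ai <- (diag(k) - G) %*% Xi
    condV <- symm(Psi - G %*% Psi)
    ev <- eigen(condV, symmetric = TRUE)
    condV <- symm(ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors)))
    V <- symm(condV + Ai %*% fit$vcov %*% t(Ai))
    espec <- if (!is.null(curves)) curves[[i]]$espec
    loc <- if (!is.null(curves)) curves[[i]]$location else i
    out[[i]] <- structure(list(eta = eta, vcov = V, espec = espec,
                               location = loc, blup = TRUE,
                               # pieces for joint (cross-location correlated)
                               # Monte Carlo sampling of the curves
                               fe_jacobian = Ai, cond_vcov = condV),
                          class = c("blup_curve", "reduced_curve"))
  }
  out
}
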
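# Independent brute-force oracles used to validate the implementation.

# Cox-de Boor recursion, written directly from the recurrence (0/0 = 0).
bspline_oracle <- function(x, degree, internal_knots, boundary) {
  ord <- degree + 1
  kn <- c(rep(boundary[1], ord), internal_knots, rep(boundary[2], ord))
  nb <- length(kn) - ord
  b0 <- function(i, x) {
    # right-closed last non-empty interval so the upper boundary is covered
    if (kn[i] < kn[i + 1] && kn[i + 1] == boundary[2])
      as.numeric(x >= kn[i] & x <= kn[i + 1])
    else
      as.numeric(x >= kn[i] & x < kn[i + 1])
  }
  rec <- function(i, k, x) {
    if (k == 0) return(b0(i, x))
    a1 <- if (kn[i + k] > kn[i])
      (x - kn[i]) / (kn[i + k] - kn[i]) * rec(i, k - 1, x) else 0
    a2 <- if (kn[i + k + 1] > kn[i + 1])
      (kn[i + k + 1] - x) / (kn[i + k + 1] - kn[i + 1]) * rec(i + 1, k - 1, x)
    else 0
    a1 + a2
  }
  sapply(seq_len(nb), function(i) rec(i, degree, x))
}

# Natural cubic spline space via the truncated power basis with natural
# constraints (linear tails), for span comparison.
ncs_truncpower <- function(x, internal_knots, boundary) {
  kn <- c(boundary[1], internal_knots, boundary[2])
  K <- length(kn)
  d <- function(k) {
    (pmax(x - kn[k], 0)^3 - pmax(x - kn[K], 0)^3) / (kn[K] - kn[k])
  }
  cbind(1, x, sapply(seq_len(K - 2), function(k) d(k) - d(K - 1)))
}

proj_mat <- function(B) B %*% solve(crossprod(B), t(B))

# Newton-Raphson Poisson log-likelihood maximiser.
newton_poisson <- function(y, X, tol = 1e-12, maxit = 100) {
  beta <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1))
  for (it in seq_len(maxit)) {
    mu <- exp(drop(X %*% beta))
    step <- solve(crossprod(X, X * mu), crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Univariate REML negative log-likelihood for a random-effects meta
# regression with design x (textbook profile form).
reml_nll_uni <- function(psi, y, s, x = matrix(1, length(y), 1)) {
  w <- 1 / (s + psi)
  XtWX <- crossprod(x, x * w)
  beta <- solve(XtWX, crossprod(x, y * w))
  r <- y - drop(x %*% beta)
  0.5 * (sum(log(s + psi)) + sum(r^2 * w) + determinant(XtWX)$modulus)
}

# Scalar day-by-day attribution loop (forward perspective).
attr_forward_loop <- function(deaths, temps, eta, espec, mmt, lag = 21) {
  n <- length(deaths)
  bref <- drop(exposure_basis(mmt, espec))
  an <- numeric(n)
  for (t in seq_len(n)) {
    b <- sum((drop(exposure_basis(temps[t], espec)) - bref) * eta)
    win <- t:min(t + lag, n)
    an[t] <- (1 - exp(-b)) * mean(deaths[win])
  }
  an
}
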
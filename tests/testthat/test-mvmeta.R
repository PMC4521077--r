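test_that("univariate REML matches a dense grid-search oracle and metafor", {
  set.seed(55)
  n <- 15
  s <- runif(n, 0.02, 0.2)
  psi_true <- 0.1
  y <- rnorm(n, 1.3, sqrt(s + psi_true))
  curves <- lapply(seq_len(n), function(i)
    make_curve(y[i], matrix(s[i], 1, 1)))
  fit <- fit_mvmeta(curves)
  grid <- seq(0, 10 * var(y), length.out = 4001)
  nll <- vapply(grid, reml_nll_uni, 0, y = y, s = s)
  expect_lt(abs(fit$Psi[1, 1] - grid[which.min(nll)]), diff(grid[1:2]) * 2)
  skip_if_not_installed("metafor")
  rma <- metafor::rma(yi = y, vi = s, method = "REML",
                      control = list(threshold = 1e-10))
  expect_equal(fit$Psi[1, 1], rma$tau2, tolerance = 1e-4)
  expect_equal(unname(fit$beta[1, 1]), unname(rma$beta[1, 1]),
               tolerance = 1e-5)
})

test_that("REML is invariant to the country-indicator parameterisation", {
  set.seed(77)
  n <- 12
  k <- 2
  y <- matrix(rnorm(n * k, c(0.5, -0.2), 0.3), n, k, byrow = TRUE)
  S <- lapply(seq_len(n), function(i) diag(runif(k, 0.01, 0.05)))
  curves <- lapply(seq_len(n), function(i) make_curve(y[i, ], S[[i]]))
  country <- rep(c("Aland", "Borduria", "Cydonia"), each = 4)
  meta1 <- data.frame(location = seq_len(n), country = country)
  meta2 <- data.frame(location = seq_len(n),
                      country = c(Aland = "Zeta", Borduria = "Borduria",
                                  Cydonia = "Cydonia")[country])
  f1 <- fit_mvmeta(curves, meta_design(meta1, "country"))
  f2 <- fit_mvmeta(curves, meta_design(meta2, "country"))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$Psi, f2$Psi, tolerance = 1e-6)
  b1 <- compute_blups(f1)
  b2 <- compute_blups(f2)
  for (i in seq_len(n))
    expect_equal(b1[[i]]$eta, b2[[i]]$eta, tolerance = 1e-6)
})

test_that("Wald test: zero block, 1-df identity, and null calibration", {
  # exact-zero coefficient block gives W = 0, p = 1
  beta <- matrix(c(0.4, 0), 2, 1, dimnames = list(c("(Intercept)", "x"), NULL))
  V <- diag(c(0.01, 0.04))
  fit0 <- make_metafit(beta, V, matrix(0.1), matrix(rnorm(5)),
                       rep(list(matrix(0.1)), 5), cbind(1, rnorm(5)))
  w0 <- wald_test(fit0, "x")
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  # 1-df statistic equals the squared z-statistic
  fit0$beta["x", 1] <- 0.3
  w1 <- wald_test(fit0, "x")
  expect_equal(w1$statistic, (0.3 / 0.2)^2, tolerance = 1e-12)
  # type-I error near nominal when the predictor is unrelated
  set.seed(99)
  n <- 20
  rej <- 0
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    s <- runif(n, 0.02, 0.08)
    y <- rnorm(n, 0.8, sqrt(s + 0.05))
    x <- rnorm(n)
    curves <- lapply(seq_len(n), function(i)
      make_curve(y[i], matrix(s[i], 1, 1)))
    X <- cbind(`(Intercept)` = 1, x = x)
    f <- fit_mvmeta(curves, X)
    rej <- rej + (wald_test(f, "x")$p_value < 0.05)
  }
  expect_gte(rej / n_rep, 0.02)
  expect_lte(rej / n_rep, 0.08)
})

test_that("Cochran Q and I2: degenerate case and univariate formula", {
  # identical estimates, intercept design: Q = 0, I2 = 0
  curves_id <- lapply(1:6, function(i)
    make_curve(c(0.2, -0.1), diag(c(0.02, 0.03))))
  h0 <- cochran_q_i2(curves_id)
  expect_equal(h0$Q, 0, tolerance = 1e-10)
  expect_equal(h0$I2, 0)
  # univariate case matches the textbook Q
  set.seed(12)
  y <- rnorm(10, 1, 0.4)
  s <- runif(10, 0.02, 0.1)
  curves <- lapply(1:10, function(i) make_curve(y[i], matrix(s[i], 1, 1)))
  h <- cochran_q_i2(curves)
  w <- 1 / s
  mu <- sum(w * y) / sum(w)
  expect_equal(h$Q, sum(w * (y - mu)^2), tolerance = 1e-10)
  expect_equal(h$df, 9)
  expect_equal(h$I2, max(0, (h$Q - 9) / h$Q) * 100, tolerance = 1e-12)
})

test_that("BLUP limiting behaviour and shrinkage weights are exact", {
  k <- 2
  n <- 5
  set.seed(3)
  y <- matrix(rnorm(n * k), n, k)
  X <- matrix(1, n, 1)
  beta <- matrix(c(0.1, -0.2), 1, k)
  Vb <- diag(2) * 1e-4
  S <- rep(list(diag(k) * 0.05), n)
  # Psi = 0: every BLUP equals the fixed-effect prediction
  f0 <- make_metafit(beta, Vb, matrix(0, k, k), y, S, X)
  for (b in compute_blups(f0)) expect_equal(b$eta, drop(beta), tolerance = 1e-12)
  # S_i = 0: BLUP equals the location estimate exactly
  fS <- make_metafit(beta, Vb, diag(k) * 0.3, y,
                     rep(list(matrix(0, k, k)), n), X)
  bl <- compute_blups(fS)
  for (i in seq_len(n)) expect_equal(bl[[i]]$eta, y[i, ], tolerance = 1e-12)
  # scalar case with S = Psi: the BLUP is the midpoint
  fm <- make_metafit(matrix(0.5), matrix(1e-6), matrix(0.2),
                     matrix(1.5), list(matrix(0.2)), matrix(1))
  expect_equal(compute_blups(fm)[[1]]$eta, (1.5 + 0.5) / 2, tolerance = 1e-12)
  # shrinkage monotonicity: larger S_i pulls towards the prediction
  d_for <- function(s_i) {
    f <- make_metafit(matrix(0.5), matrix(1e-6), matrix(0.2),
                      matrix(1.5), list(matrix(s_i)), matrix(1))
    abs(compute_blups(f)[[1]]$eta - 0.5)
  }
  ds <- vapply(c(0.01, 0.1, 0.5, 2), d_for, 0)
  expect_true(all(diff(ds) < 0))
})

test_that("BLUPs borrow information: lower MSE than raw estimates for
           imprecise locations", {
  set.seed(404)
  n <- 30
  psi <- 0.02
  mse_raw <- mse_blup <- 0
  for (r in 1:40) {
    truth <- rnorm(n, 1, sqrt(psi))
    s <- c(rep(0.3, 10), rep(0.01, 20))   # 10 small-count locations
    y <- rnorm(n, truth, sqrt(s))
    curves <- lapply(seq_len(n), function(i)
      make_curve(y[i], matrix(s[i], 1, 1)))
    f <- fit_mvmeta(curves)
    bl <- compute_blups(f)
    est <- vapply(bl, `[[`, 0, "eta")
    mse_raw <- mse_raw + mean((y[1:10] - truth[1:10])^2)
    mse_blup <- mse_blup + mean((est[1:10] - truth[1:10])^2)
  }
  expect_lt(mse_blup, mse_raw)
})

test_that("meta-design construction validates and reference-codes", {
  meta <- data.frame(location = 1:6,
                     country = c("B", "A", "B", "C", "A", "C"),
                     avg_tmean = rnorm(6, 14), range_tmean = runif(6, 20, 30))
  X <- meta_design(meta)
  expect_equal(colnames(X),
               c("(Intercept)", "countryB", "countryC", "avg_tmean",
                 "range_tmean"))
  expect_equal(unname(X[2, "countryB"]), 0)  # "A" is the reference
  expect_error(meta_design(meta, "humidity"), "no column")
  expect_error(fit_mvmeta(lapply(1:4, function(i)
    make_curve(rnorm(1), matrix(0.1))), X[1:4, ]), "more locations")
})
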
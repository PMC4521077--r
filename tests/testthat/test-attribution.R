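# Shared fixture: a realistic exposure spec, a curve, and a 200-day series.
att_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(202)
      pool <- 14 + 9 * cos(2 * pi * (1:3650) / 365) + rnorm(3650, 0, 2)
      espec <- exposure_basis_spec(pool)
      # curve approximating a V shape with minimum near 19 degrees
      grid <- seq(min(pool), max(pool), length.out = 200)
      target <- ifelse(grid < 19, 0.015 * (19 - grid), 0.02 * (grid - 19)^2)
      eta <- qr.solve(exposure_basis(grid, espec), target)
      V <- crossprod(matrix(rnorm(25, 0, 0.01), 5)) + diag(5) * 1e-5
      curve <- make_curve(eta, V, espec, "locA")
      temps <- pool[1001:1200]
      deaths <- rpois(200, 30)
      cache <<- list(pool = pool, espec = espec, curve = curve,
                     series = data.frame(
                       date = seq(as.Date("2003-01-01"), by = "day",
                                  length.out = 200),
                       deaths = deaths, tmean = temps))
    }
    cache
  }
})

test_that("MMT search equals exhaustive evaluation and handles shapes", {
  fx <- att_fixture()
  mmt <- find_mmt(fx$curve, fx$pool)
  # independent exhaustive evaluation over the whole percentile grid
  tg <- quantile(fx$pool, (1:99) / 100, type = 7, names = FALSE)
  vals <- drop(exposure_basis(tg, fx$espec) %*% fx$curve$eta)
  expect_equal(mmt$mmt, tg[which.min(vals)])
  expect_equal(mmt$mmt_percentile, which.min(vals))
  expect_true(mmt$mmt_percentile >= 1 && mmt$mmt_percentile <= 99)
  # strictly increasing curve: minimum at the search lower bound
  grid <- seq(min(fx$pool), max(fx$pool), length.out = 200)
  eta_up <- qr.solve(exposure_basis(grid, fx$espec), 0.01 * grid)
  up <- make_curve(eta_up, diag(5) * 1e-4, fx$espec)
  expect_equal(find_mmt(up, fx$pool)$mmt_percentile, 1)
  # symmetric U around the median lands at the 50th percentile
  med <- quantile(fx$pool, 0.5, type = 7, names = FALSE)
  eta_u <- qr.solve(exposure_basis(grid, fx$espec), (grid - med)^2 * 0.01)
  uu <- make_curve(eta_u, diag(5) * 1e-4, fx$espec)
  expect_equal(find_mmt(uu, fx$pool)$mmt_percentile, 50)
  expect_error(find_mmt(fx$curve, rep(10, 500)), "degenerate")
  expect_error(find_mmt(fx$curve, fx$pool[1:50]), "at least 100")
})

test_that("daily cumulative log-RR is centred and consistent with predict_curve", {
  fx <- att_fixture()
  mmt <- find_mmt(fx$curve, fx$pool)
  b <- cumulative_logrr_series(fx$series$tmean, fx$curve, mmt)
  pc <- predict_curve(fx$curve$eta, fx$curve$vcov, fx$espec,
                      at = fx$series$tmean, ref = mmt$mmt)
  expect_lt(max(abs(b - pc$logrr)), 1e-12)
  expect_equal(cumulative_logrr_series(rep(mmt$mmt, 10), fx$curve, mmt),
               rep(0, 10))
  null <- make_curve(rep(0, 5), diag(5) * 1e-6, fx$espec)
  expect_equal(cumulative_logrr_series(fx$series$tmean, null, mmt),
               rep(0, 200))
})

test_that("forward attribution matches the scalar day-by-day loop", {
  fx <- att_fixture()
  mmt <- find_mmt(fx$curve, fx$pool)
  att <- attributable_forward(fx$series, fx$curve, mmt)
  loop <- attr_forward_loop(fx$series$deaths, fx$series$tmean,
                            fx$curve$eta, fx$espec, mmt$mmt)
  expect_lt(max(abs(att$an - loop)), 1e-12)
  expect_equal(att$an_total, sum(loop), tolerance = 1e-12)
  expect_equal(att$af_total, sum(loop) / sum(fx$series$deaths),
               tolerance = 1e-12)
  # all days at the MMT attribute nothing
  s0 <- data.frame(deaths = rpois(100, 20), tmean = rep(mmt$mmt, 100))
  expect_equal(attributable_forward(s0, fx$curve, mmt)$an_total, 0)
  # constant log-RR b with constant deaths: AF is exactly 1 - exp(-b)
  x2 <- 5
  sc <- data.frame(deaths = rep(40, 400), tmean = rep(x2, 400))
  b2 <- cumulative_logrr_series(x2, fx$curve, mmt = 19)
  af2 <- attributable_forward(sc, fx$curve, mmt = 19)
  expect_equal(af2$af_total, 1 - exp(-b2), tolerance = 1e-12)
  # dropping incomplete windows zeroes the final lag days
  attd <- attributable_forward(fx$series, fx$curve, mmt, incomplete = "drop")
  expect_true(all(attd$an[180:200] == 0))
  expect_error(attributable_forward(fx$series[0, ], fx$curve, mmt), "empty")
})

test_that("AF is invariant to uniform death-count scaling", {
  fx <- att_fixture()
  mmt <- find_mmt(fx$curve, fx$pool)
  a1 <- attributable_forward(fx$series, fx$curve, mmt)
  s3 <- fx$series
  s3$deaths <- s3$deaths * 3L
  a3 <- attributable_forward(s3, fx$curve, mmt)
  expect_equal(a3$af_total, a1$af_total, tolerance = 1e-12)
  expect_equal(a3$an, a1$an * 3, tolerance = 1e-12)
})

test_that("component splits partition the total exactly", {
  fx <- att_fixture()
  mmt <- find_mmt(fx$curve, fx$pool)
  att <- attributable_forward(fx$series, fx$curve, mmt)
  co <- range_cutoffs(fx$series$tmean, extra = c(10, 25, 50, 75, 90))
  sp <- split_components(att$an, fx$series$tmean, mmt, co,
                         att$deaths_total)
  expect_equal(sp$cold + sp$heat, sp$total, tolerance = 1e-12)
  expect_equal(sp$extreme_cold + sp$moderate_cold, sp$cold, tolerance = 1e-12)
  expect_equal(sp$extreme_heat + sp$moderate_heat, sp$heat, tolerance = 1e-12)
  expect_equal(sum(sp$ranges$an), sp$total, tolerance = 1e-12)
  # filter oracle for the extreme-cold share
  qlo <- quantile(fx$series$tmean, 0.025, type = 7, names = FALSE)
  expect_equal(sp$extreme_cold,
               sum(att$an[fx$series$tmean < pmin(qlo, mmt$mmt)]),
               tolerance = 1e-12)
  # all temperatures below the reference: everything is cold
  warm_ref <- max(fx$series$tmean) + 1
  spc <- split_components(att$an, fx$series$tmean, warm_ref,
                          range_cutoffs(fx$series$tmean))
  expect_equal(spc$heat, 0)
  expect_equal(spc$cold, spc$total, tolerance = 1e-12)
})

test_that("Monte Carlo eCIs are deterministic and collapse when V = 0", {
  fx <- att_fixture()
  mmt <- find_mmt(fx$curve, fx$pool)
  degenerate <- make_curve(fx$curve$eta, matrix(0, 5, 5), fx$espec, "locA")
  att <- attributable_forward(fx$series, degenerate, mmt)
  e0 <- monte_carlo_eci(list(fx$series), list(degenerate), list(mmt),
                        countries = "X", n_sim = 150, seed = 5)
  tot <- e0$total[e0$total$component == "total", ]
  expect_equal(tot$an_low, att$an_total, tolerance = 1e-10)
  expect_equal(tot$an_high, att$an_total, tolerance = 1e-10)
  e1 <- monte_carlo_eci(list(fx$series), list(fx$curve), list(mmt),
                        countries = "X", n_sim = 150, seed = 5)
  e2 <- monte_carlo_eci(list(fx$series), list(fx$curve), list(mmt),
                        countries = "X", n_sim = 150, seed = 5)
  expect_identical(e1, e2)
  e3 <- monte_carlo_eci(list(fx$series), list(fx$curve), list(mmt),
                        countries = "X", n_sim = 150, seed = 6)
  expect_false(identical(e1$total, e3$total))
  expect_error(monte_carlo_eci(list(fx$series), list(fx$curve), list(mmt),
                               countries = "X", n_sim = 50), "at least 100")
})
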
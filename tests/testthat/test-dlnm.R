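# independent Cox-de Boor recursion used as the spline oracle
deboor_basis <- function(x, knots, degree, boundary) {
  kv <- c(rep(boundary[1], degree + 1), knots, rep(boundary[2], degree + 1))
  nb <- length(kv) - degree - 1
  one <- function(i, d, t) {
    if (d == 0) {
      hi <- if (i + 1 == length(kv) - degree) kv[i + 1] + 1e-12 else kv[i + 1]
      return(as.numeric(t >= kv[i] & t < hi))
    }
    a <- if (kv[i + d] > kv[i])
      (t - kv[i]) / (kv[i + d] - kv[i]) * one(i, d - 1, t) else 0
    b <- if (kv[i + d + 1] > kv[i + 1])
      (kv[i + d + 1] - t) / (kv[i + d + 1] - kv[i + 1]) * one(i + 1, d - 1, t) else 0
    a + b
  }
  vapply(seq_len(nb), function(i) one(i, degree, x), numeric(length(x)))
}

test_that("bspline_design is a partition of unity matching a de Boor oracle", {
  set.seed(5)
  x <- runif(100)
  B <- bspline_design(x, knots = c(0.3, 0.6), degree = 2L, boundary = c(0, 1))
  expect_equal(rowSums(B), rep(1, 100), tolerance = 1e-12)
  expect_identical(ncol(B), 5L)  # interior + degree + 1

  O <- deboor_basis(x, c(0.3, 0.6), 2L, c(0, 1))
  expect_equal(unname(B), unname(O), tolerance = 1e-12)

  # degree 0 with one knot is the indicator basis
  B0 <- bspline_design(c(0.25, 0.75), knots = 0.5, degree = 0L,
                       boundary = c(0, 1))
  expect_equal(unname(B0), rbind(c(1, 0), c(0, 1)), tolerance = 1e-12)

  expect_error(bspline_design(2, knots = 0.5, degree = 2L, boundary = c(0, 1)),
               "outside")
  expect_error(bspline_design(0.5, knots = c(0.6, 0.4), degree = 2L,
                              boundary = c(0, 1)), "increasing")
})

test_that("the cross-basis has the right shape and degenerate behaviour", {
  cfg <- run_config()
  temp <- simulate_temperature(400, synth_truth(), seed = 31)
  cb <- build_cross_basis(temp, cfg)
  nv <- length(cfg$dlnm$var_knot_probs) + cfg$dlnm$var_degree  # intercept dropped
  nl <- ncol(cb$B_lag)
  expect_identical(ncol(cb$Q), nv * nl)
  expect_identical(sum(!cb$complete), cfg$dlnm$max_lag)

  # constant temperature: all complete rows identical
  const <- daily_series(temp$date, rep(10, 400), "temperature")
  cbc <- build_cross_basis(const, cfg, var_knots = c(8, 10.5, 12),
                           var_boundary = c(0, 20))
  Qc <- cbc$Q[cbc$complete, ]
  expect_lt(max(abs(sweep(Qc, 2, Qc[1, ]))), 1e-12)

  # lag range 0..0 reduces to the var basis of the current temperature
  cfg0 <- run_config(dlnm = list(max_lag = 0L))
  cb0 <- build_cross_basis(temp, cfg0)
  V <- bspline_design(temp$value, cb0$var_knots, cfg$dlnm$var_degree,
                      cb0$var_boundary)[, -1]
  expect_equal(unname(cb0$Q), unname(V), tolerance = 1e-12)

  expect_error(build_cross_basis(temp$value[1:10], cfg), "longer")
})

test_that("seasonal harmonics and the trend spline meet their contracts", {
  dates <- seq(as.Date("1981-01-01"), as.Date("2011-12-31"), by = "day")
  H <- seasonal_harmonics(dates, 4L)
  expect_identical(ncol(H), 8L)
  expect_true(all(H >= -1 & H <= 1))
  # fundamental sine crosses zero about twice per year
  crossings <- sum(H[-1, 1] * H[-nrow(H), 1] < 0)
  expect_lt(abs(crossings - 2 * 31), 3)

  tr31 <- trend_spline(dates, 1)
  expect_identical(attr(tr31, "df"), 3L)
  expect_identical(qr(cbind(1, tr31))$rank, 4L)  # full rank with intercept
  tr5 <- trend_spline(seq(as.Date("2007-01-01"), as.Date("2011-12-31"), "day"), 1)
  expect_identical(attr(tr5, "df"), 1L)
  # re-evaluation at the training dates reproduces the basis
  expect_equal(trend_spline_predict(tr31, dates), unclass(tr31)[, ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("quasi-Poisson IRLS matches closed forms and estimates dispersion", {
  # intercept-only closed form
  y <- c(2, 5, 9, 1, 0, 4)
  f <- fit_quasipoisson(y, matrix(1, 6, 1))
  expect_equal(exp(f$coefficients[1]), mean(y), tolerance = 1e-10)

  # dispersion close to 1 for genuinely Poisson data
  disp <- vapply(1:50, function(s) {
    sim <- wxmort:::with_seed(s, {
      X <- cbind(1, rnorm(5000), rnorm(5000))
      eta <- drop(X %*% c(2, 0.2, -0.1))
      list(X = X, y = rpois(5000, exp(eta)))
    })
    fit_quasipoisson(sim$y, sim$X)$dispersion
  }, numeric(1))
  expect_lt(abs(median(disp) - 1), 0.1)

  expect_error(fit_quasipoisson(c(1, 2), cbind(c(1, 1), c(2, 2))), "rank")
})

test_that("the overall cumulative RR curve meets its analytic contracts", {
  sim <- small_sim(n_days = 1500, seed = 91)
  fit <- fit_dlnm(sim$mort, sim$temp, run_config())

  rr <- overall_cumulative_rr(fit, reference = 0)
  i0 <- which.min(abs(rr$temp - 0))
  # at (or nearest to) the reference the curve passes through 1
  rr0 <- overall_cumulative_rr(fit, grid = c(-5, 0, 5), reference = 0)
  expect_equal(rr0$rr[2], 1, tolerance = 1e-12)
  expect_equal(rr0$lo95[2], 1, tolerance = 1e-12)
  expect_equal(rr0$hi95[2], 1, tolerance = 1e-12)
  expect_true(all(rr$lo95 <= rr$rr & rr$rr <= rr$hi95))

  # reference choice only shifts the curve: log-RR differences identical
  ra <- overall_cumulative_rr(fit, grid = seq(-10, 20, 2), reference = 0)
  rb <- overall_cumulative_rr(fit, grid = seq(-10, 20, 2), reference = 10)
  expect_equal(diff(log(ra$rr)), diff(log(rb$rr)), tolerance = 1e-10)

  # zero cross-basis coefficients: flat curve with degenerate bands
  fit0 <- fit
  fit0$coefficients[fit0$blocks$cb] <- 0
  fit0$vcov[fit0$blocks$cb, ] <- 0
  fit0$vcov[, fit0$blocks$cb] <- 0
  rz <- overall_cumulative_rr(fit0, reference = 0)
  expect_equal(rz$rr, rep(1, nrow(rz)), tolerance = 1e-12)
  expect_equal(rz$lo95, rep(1, nrow(rz)), tolerance = 1e-12)

  expect_error(overall_cumulative_rr(fit, reference = 100), "outside")
  expect_error(overall_cumulative_rr(fit, grid = seq(-100, 0, 10)), "outside")
})

test_that("out-of-sample DLNM predictions track the true expectation", {
  truth <- synth_truth()
  temp <- simulate_temperature(2200, truth, seed = 13)
  mort <- simulate_mortality(temp, truth, seed = 14, return_mu = TRUE)
  fit <- fit_dlnm(mort, temp, run_config())
  tail_start <- temp$date[1800]
  pr <- predict(fit, newdata = list(temp = wxmort:::window_daily(
    temp, tail_start, temp$date[2200])))
  expect_identical(nrow(pr), 2200L - 1800L + 1L - 21L)
  mu <- attr(mort, "mu")[match(pr$date, mort$date)]
  expect_gt(cor(pr$mu, mu), 0.9)
})
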
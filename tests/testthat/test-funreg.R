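test_that("base learner degrees of freedom are calibrated exactly", {
  x <- seq(0, 1, length.out = 300)
  for (df in c(2.5, 4, 6)) {
    l <- pspline_learner(x, n_knots = 8, df = df)
    S <- l$X %*% chol2inv(l$K_chol) %*% t(l$X)
    expect_equal(sum(diag(S)), df, tolerance = 1e-6)
  }
  # unpenalized learner: df equals the column count
  lu <- base_learner(cbind(1, x), NULL, name = "lin")
  expect_identical(lu$df, 2L)
  expect_error(base_learner(cbind(1, x), diag(2), df = 3, name = "bad"),
               "unreachable")
})

test_that("boosting converges to OLS with one linear learner and never increases loss", {
  sim <- wxmort:::with_seed(41, {
    x <- rnorm(100)
    list(x = x, y = 1 + 2 * x + rnorm(100))
  })
  X <- cbind(1, sim$x)
  bf <- boost(sim$y, list(base_learner(X, NULL, name = "lin")),
              family = "gaussian", nu = 0.1, mstop = 10000)
  ols <- lm.fit(X, sim$y)$coefficients
  est <- bf$coef$lin + c(bf$f0, 0)
  expect_lt(sqrt(sum((est - ols)^2)), 1e-3)
  expect_true(all(diff(bf$losses) <= 1e-9))

  # mstop = 0 is the offset-only model: constant exp-mean for Poisson
  yp <- wxmort:::with_seed(42, rpois(50, 7))
  b0 <- boost(yp, list(base_learner(matrix(rnorm(50)), NULL, name = "x")),
              family = "poisson", nu = 0.1, mstop = 0)
  expect_equal(exp(b0$f), rep(mean(yp), 50), tolerance = 1e-12)

  # Poisson training loss is also monotone under the scaled gradient
  Xp <- cbind(1, rnorm(50))
  bp <- boost(yp, list(base_learner(Xp, NULL, name = "lin")),
              family = "poisson", nu = 0.1, mstop = 200)
  expect_true(all(diff(bp$losses) <= 1e-9))
})

test_that("cv_mstop is reproducible and reacts to signal strength", {
  sim <- wxmort:::with_seed(43, {
    x <- rnorm(600)
    list(x = x, y = rpois(600, exp(2 + 0.3 * x)))
  })
  l <- list(base_learner(cbind(sim$x), NULL, name = "lin"))
  cv1 <- cv_mstop(sim$y, l, unit_id = 1:600, family = "poisson", seed = 9)
  cv2 <- cv_mstop(sim$y, l, unit_id = 1:600, family = "poisson", seed = 9)
  expect_identical(cv1$mstop, cv2$mstop)
  expect_gt(cv1$mstop, 10L)  # strong signal wants many iterations

  ynull <- wxmort:::with_seed(44, rpois(600, 7))
  cvn <- cv_mstop(ynull, l, unit_id = 1:600, family = "poisson", seed = 9)
  expect_lt(cvn$mstop, cv1$mstop)
})

test_that("the FY model fits annual curves and its cumulative curve follows the surface", {
  truth <- synth_truth()
  temp <- simulate_temperature(days_in_span("1991-01-01", "1998-12-31"),
                               truth, seed = 45, start = as.Date("1991-01-01"))
  mort <- simulate_mortality(temp, truth, seed = 46)
  fit <- fit_fy(to_year_curves(mort), to_year_curves(temp), run_config())

  expect_identical(dim(fit$beta), c(31L, 365L))
  rr <- fy_cumulative_rr(fit, boot = 0)
  expect_identical(nrow(rr), 365L)
  expect_equal(rr$rr, exp(colSums(fit$beta)), tolerance = 1e-12)

  # closed forms on a manipulated surface
  fit0 <- fit
  fit0$beta[] <- 0
  expect_equal(fy_cumulative_rr(fit0, boot = 0)$rr, rep(1, 365),
               tolerance = 1e-12)
  fit0$beta[] <- 0.003
  expect_equal(fy_cumulative_rr(fit0, boot = 0)$rr, rep(exp(31 * 0.003), 365),
               tolerance = 1e-12)
  fit0$beta <- matrix(rep(seq(0, 0.01, length.out = 365), each = 31),
                      31, 365)
  expect_true(all(diff(fy_cumulative_rr(fit0, boot = 0)$rr) > 0))

  # first 30 days of the first year carry no lag history
  expect_true(all(is.na(fit$mu[1, 1:30])))
  expect_true(all(is.finite(fit$mu[1, 31:365])))

  # cold winters raise mortality: the cumulative curve sits below 1 in winter
  expect_lt(mean(rr$rr[c(1:60, 330:365)]), 1)

  two_years <- function(s) {
    yc <- to_year_curves(s)
    yc$years <- yc$years[1:2]
    yc$values <- yc$values[1:2, , drop = FALSE]
    yc
  }
  expect_error(fit_fy(two_years(mort), two_years(temp), run_config()),
               "3 complete years")
})

test_that("identical seeds give identical boosted fits", {
  truth <- synth_truth()
  temp <- simulate_temperature(days_in_span("1994-01-01", "1997-12-31"),
                               truth, seed = 47, start = as.Date("1994-01-01"))
  mort <- simulate_mortality(temp, truth, seed = 48)
  f1 <- fit_fy(to_year_curves(mort), to_year_curves(temp), run_config(seed = 3))
  f2 <- fit_fy(to_year_curves(mort), to_year_curves(temp), run_config(seed = 3))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$boost$mstop, f2$boost$mstop)
})

test_that("the FD hour convention maps design columns to previous-day clock hours", {
  # an effect concentrated at hour 7 of the previous day is located there
  truth <- synth_truth()
  n <- 1200
  temp <- simulate_temperature(n, truth, seed = 49,
                               start = as.Date("2007-01-01"))
  hr <- simulate_hourly(temp, truth, seed = 50)
  hmat <- matrix(hr$value, ncol = 24, byrow = TRUE)
  beta_true <- rep(0, 24); beta_true[8] <- 0.6  # clock hour 7
  eta <- log(15) + drop(hmat %*% beta_true) / 24
  mu <- exp(c(NA, eta[-n]))
  y <- wxmort:::with_seed(51, rpois(n, ifelse(is.na(mu), 15, mu)))
  fit <- fit_fd(daily_series(temp$date, y, "count"), hr, run_config(seed = 52))
  expect_identical(length(fit$beta), 24L)
  # the smooth estimate peaks within a couple of hours of the impulse
  expect_lte(abs(which.max(fit$beta) - 1L - 7L), 2L)
  expect_identical(fit$dates[1], temp$date[2])  # first day needs history
})

test_that("flat daily curves collapse the functional term to a daily-mean effect", {
  flat <- synth_truth(diurnal_amplitude = 0, diurnal_amplitude_sd = 0,
                      diurnal_phase_sd = 0, ramp_sd = 0, hourly_noise_sd = 0)
  temp <- simulate_temperature(800, flat, seed = 53,
                               start = as.Date("2008-01-01"))
  mort <- simulate_mortality(temp, flat, seed = 54)
  hr <- simulate_hourly(temp, flat, seed = 55)
  fit <- fit_fd(mort, hr, run_config(seed = 56))
  # the functional component is an exact linear function of the previous
  # day's mean temperature
  comp <- drop(fit$data$Xf %*% fit$boost$coef$hour_curve)
  prev_mean <- temp$value[match(fit$dates - 1, temp$date)]
  r <- lm.fit(cbind(1, prev_mean), comp)$residuals
  expect_lt(max(abs(r)), 1e-6 * (1 + max(abs(comp))))
})
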
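test_that("temperature simulation is deterministic and structurally correct", {
  truth <- synth_truth()
  a <- simulate_temperature(500, truth, seed = 11)
  b <- simulate_temperature(500, truth, seed = 11)
  expect_identical(a$value, b$value)
  c2 <- simulate_temperature(500, truth, seed = 12)
  expect_false(identical(a$value, c2$value))

  # distinct seeds give (near) independent noise
  det <- simulate_temperature(8000, synth_truth(temp_ar1 = 0, temp_noise_sd = 0),
                              seed = 1)$value
  r1 <- simulate_temperature(8000, truth, seed = 1)$value - det
  r2 <- simulate_temperature(8000, truth, seed = 2)$value - det
  expect_lt(abs(cor(r1, r2)), 0.1)

  # all variability off -> constant at the mean
  flat <- synth_truth(temp_amplitude = 0, temp_trend = 0, temp_osc = list(),
                      temp_ar1 = 0, temp_noise_sd = 0, temp_mean = 10)
  expect_equal(simulate_temperature(400, flat, seed = 1)$value,
               rep(10, 400), tolerance = 1e-12)
  expect_error(simulate_temperature(100, truth, seed = 1), "366")
})

test_that("least-squares slope of simulated temperature matches the noise-free slope", {
  truth <- synth_truth(temp_trend = 0.47)
  n <- 11322
  tt <- seq_len(n)
  # noise-free component keeps the oscillations; only the AR noise is off
  base <- simulate_temperature(n, synth_truth(temp_trend = 0.47,
                                              temp_ar1 = 0,
                                              temp_noise_sd = 0), seed = 1)
  slope_free <- coef(lm.fit(cbind(1, tt), base$value))[2] * 3652.5
  slopes <- vapply(1:100, function(s) {
    x <- simulate_temperature(n, truth, seed = s)$value
    coef(lm.fit(cbind(1, tt), x))[2] * 3652.5
  }, numeric(1))
  expect_lt(abs(mean(slopes) - slope_free), 0.05)
  # the partial low-frequency oscillation cycle adds a bounded slope offset
  expect_lt(abs(slope_free - 0.47), 0.15)
})

test_that("harmonic regression on a noise-free run recovers the annual cycle", {
  truth <- quiet_temp_truth(temp_amplitude = 15.5, temp_trend = 0)
  x <- simulate_temperature(3653, truth, seed = 1)  # 10 years
  doy <- as.POSIXlt(x$date)$yday + 1
  X <- cbind(1, cos(2 * pi * doy / 365.25), sin(2 * pi * doy / 365.25))
  cf <- coef(lm.fit(X, x$value))
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  phase_doy <- (atan2(cf[3], cf[2]) * 365.25 / (2 * pi)) %% 365.25
  expect_equal(unname(amp), 15.5, tolerance = 1e-6)
  expect_equal(unname(phase_doy), 201, tolerance = 1e-4)
})

test_that("mortality counts have the configured conditional mean structure", {
  # null truth, baseline 20: sample mean within 3 Poisson standard errors
  truth <- null_truth(log_baseline = log(20))
  temp <- simulate_temperature(11322, truth, seed = 3)
  mort <- simulate_mortality(temp, truth, seed = 4)
  se <- sqrt(20 / 11322)
  expect_lt(abs(mean(mort$value) - 20), 3 * se)

  # mu is seed-independent and exactly reproducible
  m1 <- simulate_mortality(temp, truth, seed = 5, return_mu = TRUE)
  m2 <- simulate_mortality(temp, truth, seed = 6, return_mu = TRUE)
  expect_identical(attr(m1, "mu"), attr(m2, "mu"))
  expect_false(identical(m1$value, m2$value))
  expect_equal(attr(m1, "mu"), rep(20, 11322), tolerance = 1e-12)

  # Monday effect 1.2 shows up as a ratio of means
  dow <- c(1.2, rep(1, 6))
  truth_dow <- null_truth(log_baseline = log(20),
                          dow_effects = dow / exp(mean(log(dow))))
  md <- simulate_mortality(temp, truth_dow, seed = 7, return_mu = TRUE)
  wd <- as.integer(format(md$date, "%u"))
  ratio <- mean(md$value[wd == 1]) / mean(md$value)
  expect_lt(abs(ratio - 1.2 / mean(c(1.2, rep(1, 6))[wd])), 0.03)
})

test_that("hourly simulation preserves daily means and the diurnal peak", {
  truth <- synth_truth()
  daily <- simulate_temperature(400, truth, seed = 8)
  h <- simulate_hourly(daily, truth, seed = 9)
  expect_identical(nrow(h), 400L * 24L)
  m <- matrix(h$value, ncol = 24, byrow = TRUE)
  expect_equal(rowMeans(m), daily$value, tolerance = 1e-9)

  # no variability: each day is 24 copies of its mean
  flat <- synth_truth(diurnal_amplitude = 0, diurnal_amplitude_sd = 0,
                      diurnal_phase_sd = 0, ramp_sd = 0,
                      hourly_noise_sd = 0)
  hf <- simulate_hourly(daily, flat, seed = 1)
  mf <- matrix(hf$value, ncol = 24, byrow = TRUE)
  expect_equal(mf, matrix(daily$value, 400, 24), tolerance = 1e-12,
               ignore_attr = TRUE)

  # amplitude 5, no jitter: the mean diurnal profile peaks at 15:00
  amp <- synth_truth(diurnal_amplitude = 5, diurnal_amplitude_sd = 0,
                     diurnal_peak_hour = 15, diurnal_phase_sd = 0,
                     ramp_sd = 0, hourly_noise_sd = 0.5)
  ha <- simulate_hourly(daily, amp, seed = 10)
  prof <- colMeans(matrix(ha$value, ncol = 24, byrow = TRUE) - daily$value)
  expect_identical(which.max(prof) - 1L, 15L)

  # determinism
  expect_identical(simulate_hourly(daily, truth, seed = 9)$value, h$value)
})

test_that("truth_overall_rr matches closed forms and brute-force lag summation", {
  truth <- synth_truth(f = function(t) 0.01 * t)
  expect_equal(truth_overall_rr(truth, grid = 0, ref = 0)$rr, 1)
  expect_equal(truth_overall_rr(truth, grid = 10, ref = 0)$rr, exp(0.1),
               tolerance = 1e-12)
  expect_error(truth_overall_rr(truth, grid = 0:10, ref = NA), "finite")

  # brute force: sustained exposure x for all lags with weights summing to 1
  set.seed(1)
  w <- runif(22); w <- w / sum(w)
  truth_w <- synth_truth(lag_weights = w)
  f <- truth_w$mort$f
  grid <- seq(-20, 30, by = 5)
  brute <- vapply(grid, function(x)
    exp(sum(w * f(rep(x, 22))) - sum(w * f(rep(21, 22)))), numeric(1))
  expect_equal(truth_overall_rr(truth_w, grid, ref = 21)$rr, brute,
               tolerance = 1e-12)
})
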
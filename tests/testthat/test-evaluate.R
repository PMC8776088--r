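test_that("hv-block folds are one per year with a correct guard", {
  dates <- seq(as.Date("1995-01-01"), as.Date("1999-12-31"), by = "day")
  folds <- hv_folds(dates, guard_days = 0L)
  expect_identical(length(folds), 5L)
  expect_identical(vapply(folds, `[[`, integer(1), "year"), 1995:1999)
  f <- folds[[3]]
  expect_identical(sum(f$val), 365L)
  # guard 0: training is exactly everything else
  expect_true(all(xor(f$val, f$train)))

  folds30 <- hv_folds(dates, guard_days = 30L)
  f30 <- folds30[[3]]
  gap <- abs(as.numeric(outer(dates[f30$train], dates[f30$val], "-")))
  expect_gte(min(gap), 31)  # no training date within 30 days of validation
  # leakage-free: train and val (plus guard) never intersect
  expect_identical(sum(f30$train & f30$val), 0L)

  expect_error(hv_folds(dates[1:400], 0L), "2 complete")
})

test_that("rRMSE by day of year matches a direct per-day computation", {
  truth <- null_truth(log_baseline = log(12))
  temp <- simulate_temperature(days_in_span("1995-01-01", "1999-12-31"),
                               truth, seed = 61, start = as.Date("1995-01-01"))
  mort <- simulate_mortality(temp, truth, seed = 62)

  # perfect predictions: identically zero
  expect_equal(rrmse_by_doy(mort$value, mort), rep(0, 365))

  # predicting the per-day mean gives the per-day coefficient of variation
  doy <- wxmort:::doy365(mort$date)
  permean <- ave(mort$value, doy)
  got <- rrmse_by_doy(permean, mort)
  want <- vapply(1:365, function(d) {
    v <- mort$value[doy == d]
    sqrt(mean((v - mean(v))^2)) / mean(v)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  # scale invariance
  mort2 <- daily_series(mort$date, mort$value * 2L, "count")
  expect_equal(rrmse_by_doy(2 * permean, mort2), got, tolerance = 1e-12)

  # Feb 29 contributes to day 59: leap-year pooling changes only day 59
  pred <- rep(10, nrow(mort))
  base <- rrmse_by_doy(pred, mort)
  expect_identical(length(base), 365L)
  expect_true(all(is.finite(base)))
})

test_that("circular LOESS smoothing reduces noise without destroying signal", {
  expect_equal(loess_smooth(rep(3, 365), span = 0.2), rep(3, 365),
               tolerance = 1e-10)
  # local linear fits reproduce a linear curve exactly away from wrap-around
  lin <- seq(0, 1, length.out = 365)
  sm <- loess_smooth(lin, span = 0.1, circular = FALSE)
  expect_equal(sm[30:335], lin[30:335], tolerance = 1e-10)

  clean <- sin(2 * pi * (1:365) / 365)
  noisy <- clean + wxmort:::with_seed(63, rnorm(365, 0, 0.4))
  sm2 <- loess_smooth(noisy, span = 0.15)
  expect_lt(var(sm2 - clean), var(noisy - clean))
  expect_gt(cor(sm2, clean), cor(noisy, clean))
  # circular smoothing has no seam at the year boundary
  expect_lt(abs(sm2[1] - sm2[365]), 4 * 0.4 / sqrt(0.15 * 365))

  expect_error(loess_smooth(clean, span = 0), "span")
  expect_error(loess_smooth(rep(NA_real_, 365), span = 0.2), "few")
})

test_that("the comparison harness scores strategies against raw counts", {
  truth <- synth_truth()
  n <- days_in_span("1994-01-01", "1997-12-31")
  temp <- simulate_temperature(n, truth, seed = 64,
                               start = as.Date("1994-01-01"))
  mort <- simulate_mortality(temp, truth, seed = 65, return_mu = TRUE)
  cfg <- run_config(seed = 5)
  rep1 <- compare_strategies(mort, temp, strategies = c("dlnm", "oracle"),
                             cfg = cfg, mu = attr(mort, "mu"))
  expect_s3_class(rep1, "cv_report")
  expect_identical(rownames(rep1$rrmse_raw), c("dlnm", "oracle"))
  # every complete-history validation day is predicted
  expect_true(all(!is.na(rep1$predictions["oracle", ])))
  # the oracle beats the fitted model out of sample
  expect_lt(mean(rep1$rrmse_raw["oracle", ], na.rm = TRUE),
            mean(rep1$rrmse_raw["dlnm", ], na.rm = TRUE))
  # determinism under the seed
  rep2 <- compare_strategies(mort, temp, strategies = c("dlnm", "oracle"),
                             cfg = cfg, mu = attr(mort, "mu"))
  expect_identical(rep1$rrmse_raw, rep2$rrmse_raw)
  # missing inputs are a warning, not an error
  expect_warning(compare_strategies(mort, temp, strategies = c("dlnm", "fd"),
                                    cfg = cfg), "fd")
})

test_that("benchmark rRMSE shrinks with more training years", {
  truth <- synth_truth()
  score <- function(years) {
    n <- days_in_span(sprintf("%d-01-01", 2000 - years + 1), "2000-12-31")
    temp <- simulate_temperature(n, truth, seed = 66,
                                 start = as.Date(sprintf("%d-01-01",
                                                         2000 - years + 1)))
    mort <- simulate_mortality(temp, truth, seed = 67)
    rep <- compare_strategies(mort, temp, strategies = "dlnm",
                              cfg = run_config(seed = 6))
    mean(rep$rrmse_raw["dlnm", ], na.rm = TRUE)
  }
  expect_lt(score(8L), score(3L))
})
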
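#' Ground truth for the synthetic weather-mortality generator
#'
#' Bundles every parameter of the data-generating process so simulations are
#' fully specified and recovery tests have an analytic target. Defaults
#' emulate roughly three decades of daily cardiovascular deaths and daily
#' mean temperature in a cold-climate city: a strong annual temperature
#' cycle (mean 6.5 degC, amplitude 15.5 degC, July peak), a slow warming
#' trend, mid- and low-frequency oscillations (100-day and 2000-day), and
#' AR(1) weather noise; Poisson counts with winter-dominant seasonality, a
#' long-term declining trend, day-of-week effects, and a lagged U-shaped
#' temperature effect whose cold limb carries more overall risk than the
#' heat limb.
#'
#' @param temp_mean,temp_amplitude annual mean and cosine amplitude (degC).
#' @param temp_peak_doy day-of-year of the warm peak.
#' @param temp_trend warming trend, degC per decade.
#' @param temp_osc list of oscillation components, each
#'   `list(period = days, amplitude = degC, phase = radians)`.
#' @param temp_ar1,temp_noise_sd AR(1) coefficient and innovation sd of the
#'   daily weather noise (degC).
#' @param log_baseline log of the baseline daily death count.
#' @param seasonal_amp amplitude of the seasonal term on the log scale
#'   (winter-peaked).
#' @param season_peak_doy day-of-year at which mortality seasonality peaks.
#' @param trend_slope long-term mortality log-trend, per year.
#' @param dow_effects multiplicative day-of-week effects, Monday first;
#'   normalised internally to geometric mean 1.
#' @param dow_modulation optional fraction `m`: the log day-of-week effects
#'   are ramped linearly from `(1-m)` to `(1+m)` across the series, creating
#'   slowly drifting short-term confounding.
#' @param f exposure-response function on the log scale, `f(temp degC)`;
#'   the default is a piecewise-linear U with minimum at 21 degC, cold slope
#'   0.007 and heat slope 0.03 per degC.
#' @param lag_weights non-negative lag weights `w[1] = lag 0` onwards;
#'   normalised internally to sum 1.
#' @param diurnal_amplitude,diurnal_amplitude_sd mean and day-to-day sd of
#'   the diurnal cosine amplitude (degC); the daily amplitude is truncated
#'   below at 0.3 degC so every day keeps a (possibly faint) cycle.
#' @param diurnal_peak_hour,diurnal_phase_sd clock hour of the warm peak and
#'   its day-to-day jitter (hours).
#' @param ramp_sd sd of a per-day linear within-day temperature ramp
#'   (degC per hour), emulating frontal passages.
#' @param hourly_ar1,hourly_noise_sd AR(1) coefficient and innovation sd of
#'   the hour-scale weather noise (a single stream continuing across days).
#' @return A list of class `synth_truth`.
#' @export
synth_truth <- function(temp_mean = 6.5, temp_amplitude = 15.5,
                        temp_peak_doy = 201, temp_trend = 0.47,
                        temp_osc = list(
                          list(period = 100, amplitude = 1.5, phase = 0),
                          list(period = 2000, amplitude = 0.8, phase = 0.7)),
                        temp_ar1 = 0.75, temp_noise_sd = 2.5,
                        log_baseline = log(18), seasonal_amp = 0.15,
                        season_peak_doy = 15, trend_slope = -0.01,
                        dow_effects = c(1.02, 1.01, 1.00, 1.00, 1.01, 0.98, 0.98),
                        dow_modulation = 0,
                        f = function(t) 0.007 * pmax(21 - t, 0) + 0.03 * pmax(t - 21, 0),
                        lag_weights = exp(-(0:21) / 5),
                        diurnal_amplitude = 4, diurnal_amplitude_sd = 2,
                        diurnal_peak_hour = 15, diurnal_phase_sd = 1.5,
                        ramp_sd = 0.3, hourly_ar1 = 0.8,
                        hourly_noise_sd = 1.5) {
  stopifnot(length(dow_effects) == 7L, all(dow_effects > 0),
            all(lag_weights >= 0), sum(lag_weights) > 0,
            is.function(f), temp_noise_sd >= 0, hourly_noise_sd >= 0,
            diurnal_amplitude_sd >= 0, diurnal_phase_sd >= 0, ramp_sd >= 0,
            abs(temp_ar1) < 1, abs(hourly_ar1) < 1)
  dow_effects <- dow_effects / exp(mean(log(dow_effects)))
  lag_weights <- lag_weights / sum(lag_weights)
  structure(list(
    temp = list(mean = temp_mean, amplitude = temp_amplitude,
                peak_doy = temp_peak_doy, trend = temp_trend,
                osc = temp_osc, ar1 = temp_ar1, noise_sd = temp_noise_sd),
    mort = list(log_baseline = log_baseline, seasonal_amp = seasonal_amp,
                season_peak_doy = season_peak_doy, trend_slope = trend_slope,
                dow_effects = dow_effects, dow_modulation = dow_modulation,
                f = f, lag_weights = lag_weights),
    hourly = list(amplitude = diurnal_amplitude,
                  amplitude_sd = diurnal_amplitude_sd,
                  peak_hour = diurnal_peak_hour,
                  phase_sd = diurnal_phase_sd,
                  ramp_sd = ramp_sd, ar1 = hourly_ar1,
                  noise_sd = hourly_noise_sd)),
    class = "synth_truth")
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("<synth_truth>\n")
  cat(sprintf("  temperature: mean %.1f, amplitude %.1f degC, trend %.2f degC/decade, AR1 %.2f\n",
              x$temp$mean, x$temp$amplitude, x$temp$trend, x$temp$ar1))
  cat(sprintf("  mortality: baseline %.1f/day, seasonal amp %.2f (log), trend %.3f/yr, %d lags\n",
              exp(x$mort$log_baseline), x$mort$seasonal_amp,
              x$mort$trend_slope, length(x$mort$lag_weights)))
  invisible(x)
}

#' Simulate a daily temperature series
#'
#' Deterministic given the seed. The series is the sum of an annual cosine,
#' a linear warming trend, the configured mid/low-frequency oscillations and
#' stationary AR(1) noise.
#'
#' @param n_days number of days (>= 366).
#' @param truth a [synth_truth()].
#' @param seed integer seed.
#' @param start first calendar date.
#' @return A temperature [daily_series()].
#' @export
simulate_temperature <- function(n_days, truth = synth_truth(), seed = 1L,
                                 start = as.Date("1981-01-01")) {
  stopifnot(inherits(truth, "synth_truth"))
  if (n_days < 366) stop("'n_days' must be at least 366")
  dates <- as.Date(start) + seq_len(n_days) - 1L
  mu <- temp_deterministic(dates, truth)
  noise <- with_seed(seed, {
    tp <- truth$temp
    if (tp$noise_sd == 0) rep(0, n_days) else {
      innov <- rnorm(n_days, 0, tp$noise_sd)
      x <- as.numeric(stats::filter(innov, tp$ar1, method = "recursive",
                                    init = rnorm(1, 0, tp$noise_sd / sqrt(1 - tp$ar1^2))))
      x
    }
  })
  daily_series(dates, mu + noise, "temperature")
}

## Noise-free component of the temperature process
temp_deterministic <- function(dates, truth) {
  tp <- truth$temp
  t_idx <- seq_along(dates) - 1L
  doy <- as.POSIXlt(dates)$yday + 1L
  out <- tp$mean +
    tp$amplitude * cos(2 * pi * (doy - tp$peak_doy) / 365.25) +
    tp$trend * t_idx / 3652.5
  for (o in tp$osc)
    out <- out + o$amplitude * sin(2 * pi * t_idx / o$period +
                                     (if (is.null(o$phase)) 0 else o$phase))
  out
}

## Expected daily death rate mu_t implied by the truth, given a temperature
## series.  Lag weights are truncated and renormalised over the available
## history for the first days so the series stays contiguous.
mortality_mu <- function(temp, truth) {
  mt <- truth$mort
  g <- mt$f(temp$value)
  w <- mt$lag_weights
  L <- length(w) - 1L
  n <- nrow(temp)
  expo <- as.numeric(stats::filter(g, w, method = "convolution", sides = 1L))
  for (t in seq_len(min(L, n))) {
    wk <- w[seq_len(t)]
    expo[t] <- sum(wk / sum(wk) * g[t - seq_along(wk) + 1L])
  }
  t_idx <- seq_len(n) - 1L
  doy <- as.POSIXlt(temp$date)$yday + 1L
  wd <- as.integer(format(temp$date, "%u"))  # Monday = 1
  log_dow <- log(mt$dow_effects)[wd]
  if (mt$dow_modulation != 0) {
    ramp <- 1 + mt$dow_modulation * (2 * t_idx / max(t_idx, 1L) - 1)
    log_dow <- log_dow * ramp
  }
  log_mu <- mt$log_baseline +
    mt$seasonal_amp * cos(2 * pi * (doy - mt$season_peak_doy) / 365.25) +
    mt$trend_slope * t_idx / 365.25 +
    log_dow + expo
  exp(log_mu)
}

#' Simulate a daily mortality count series
#'
#' Draws `Poisson(mu_t)` counts where `log mu_t` combines the baseline,
#' winter-peaked seasonality, long-term trend, day-of-week effects and the
#' lag-weighted exposure response applied to the supplied temperature.
#'
#' @param temp a temperature [daily_series()].
#' @param truth a [synth_truth()].
#' @param seed integer seed.
#' @param return_mu if `TRUE`, attach the true expectation as attribute
#'   `"mu"` for recovery tests.
#' @return A count [daily_series()].
#' @export
simulate_mortality <- function(temp, truth = synth_truth(), seed = 1L,
                               return_mu = FALSE) {
  stopifnot(inherits(temp, "daily_series"), inherits(truth, "synth_truth"))
  mu <- mortality_mu(temp, truth)
  y <- with_seed(seed, rpois(length(mu), mu))
  out <- daily_series(temp$date, y, "count")
  if (return_mu) attr(out, "mu") <- mu
  out
}

#' Simulate an hourly temperature series around daily means
#'
#' Each day receives 24 values: the daily mean plus a diurnal cosine whose
#' amplitude and peak hour vary from day to day, a per-day linear ramp
#' (frontal passages), and autocorrelated hour-scale weather noise running
#' continuously across days. The within-day deviation is centred so the
#' daily mean of the output reproduces the input value exactly (to
#' numerical precision). The day-to-day variation of the within-day shape
#' is what makes hour-specific exposure effects identifiable; with all
#' variability parameters at zero, every day is 24 copies of its mean.
#'
#' @param daily a daily temperature [daily_series()].
#' @param truth a [synth_truth()].
#' @param seed integer seed.
#' @return An [hourly_series()] with `24 * nrow(daily)` values.
#' @export
simulate_hourly <- function(daily, truth = synth_truth(), seed = 1L) {
  stopifnot(inherits(daily, "daily_series"), inherits(truth, "synth_truth"))
  hp <- truth$hourly
  n <- nrow(daily)
  h <- 0:23
  dev <- with_seed(seed, {
    A <- if (hp$amplitude_sd == 0) rep(hp$amplitude, n) else
      pmax(rnorm(n, hp$amplitude, hp$amplitude_sd), 0.3 * (hp$amplitude > 0))
    ph <- if (hp$phase_sd == 0) rep(hp$peak_hour, n) else
      rnorm(n, hp$peak_hour, hp$phase_sd)
    ramp <- if (hp$ramp_sd == 0) rep(0, n) else rnorm(n, 0, hp$ramp_sd)
    E <- if (hp$noise_sd == 0) matrix(0, n, 24L) else
      matrix(as.numeric(stats::filter(rnorm(n * 24L, 0, hp$noise_sd),
                                      hp$ar1, method = "recursive")),
             n, 24L, byrow = TRUE)
    A * cos(2 * pi * outer(-ph, h, "+") / 24) +
      outer(ramp, h - 11.5) + E
  })
  dev <- dev - rowMeans(dev)          # mean-zero within each day
  vals <- dev + daily$value
  ts <- as.POSIXct(rep(daily$date, each = 24L), tz = "UTC") +
    3600 * rep(h, n)
  hourly_series(ts, as.vector(t(vals)))
}

#' True overall cumulative relative risk curve
#'
#' Analytic target for recovery tests: with lag weights summing to one, a
#' sustained exposure at temperature `x` multiplies the death rate by
#' `exp(f(x) - f(ref))` relative to the reference temperature.
#'
#' @param truth a [synth_truth()].
#' @param grid temperature grid (degC).
#' @param ref reference temperature (degC).
#' @return A data frame with columns `temp` and `rr`.
#' @export
truth_overall_rr <- function(truth, grid, ref) {
  stopifnot(inherits(truth, "synth_truth"), is.finite(ref))
  data.frame(temp = grid, rr = exp(truth$mort$f(grid) - truth$mort$f(ref)))
}
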
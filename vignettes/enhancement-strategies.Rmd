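---
title: "Data-enhancement strategies for weather-related health time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-enhancement strategies for weather-related health time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wxmort)
```

## The problem

Daily time series of health counts (here: cardiovascular deaths) and weather
exposures (daily-mean and hourly temperature) are the workhorse design of
environmental epidemiology, but a regression of raw daily counts on raw daily
temperature only sees one time scale. `wxmort` implements four
*data-enhancement* strategies that transform the series before regression so
that other scales become visible, together with a benchmark distributed lag
non-linear model (DLNM) and a blocked cross-validation harness that compares
them all on the raw count scale:

* **AG** — aggregate the *response* with a causal Epanechnikov kernel to
  suppress short-term confounding (day-of-week patterns) without assuming it
  is constant over decades, then fit the DLNM to the aggregated response and
  an AR model to the leftover autocorrelation.
* **EMDR** — decompose the *exposure* into intrinsic mode functions (IMFs)
  by noise-assisted multivariate empirical mode decomposition, then let a
  Poisson Lasso decide which time scales predict mortality.
* **FY** — treat each year as a single functional observation and fit a
  functional historical model: the log death rate at day-of-year `t` depends
  on the temperature history over the previous 30 days through a smooth
  surface `beta(lag, t)`, fitted by component-wise gradient boosting.
* **FD** — treat each day's 24 hourly temperatures as a functional predictor
  of the next day's death count through a smooth hourly coefficient
  `beta(hour)`.

Because administrative mortality data cannot be redistributed, the package
ships a fully parameterised synthetic generator (`synth_truth()`,
`simulate_temperature()`, `simulate_mortality()`, `simulate_hourly()`) whose
known ground truth makes every strategy testable end to end.

## The synthetic study conditions

The generator emulates roughly three decades of data from a cold-climate
city. Its defaults are fixed once and shared by the test-suite and the
acceptance script:

* **Temperature** — annual mean 6.5 °C with a 15.5 °C cosine amplitude
  peaking around day 201 (late July); a linear warming trend of 0.47 °C per
  decade; mid- and low-frequency oscillations (periods 100 and 2000 days)
  emulating synoptic and multi-annual variability; stationary AR(1) noise
  (coefficient 0.75, innovation sd 2.5 °C). A 31-year series therefore
  carries variance at every scale the EMDR strategy is meant to separate.
* **Mortality** — Poisson counts around 18 deaths/day with winter-dominant
  seasonality (log-amplitude 0.15, peak mid-January), a slow long-term
  decline (−0.01/year on the log scale), multiplicative day-of-week effects
  (weekends about 3% below weekdays, geometric mean 1), and a lagged
  U-shaped temperature effect: minimum at 21 °C, cold slope 0.007 and heat
  slope 0.03 per °C on the log scale, distributed over lags 0–21 days with
  exponentially decaying weights. The steeper total cold contribution makes
  direction-of-effect tests meaningful for a cold climate. At the start of
  the series, truncated lag weights are renormalised rather than dropping
  days, keeping every series contiguous.
* **Hourly layer** — each day adds a diurnal cosine whose amplitude
  (mean 4 °C, sd 2 °C) and peak hour (15:00 ± 1.5 h) vary from day to day,
  a per-day linear ramp (sd 0.3 °C/h) standing in for frontal passages, and
  hour-scale AR(1) noise (coefficient 0.8, innovation sd 1.5 °C) running
  continuously across days. The within-day deviation is centred so the
  hourly series always averages back to the daily series. This day-to-day
  variation of the *shape* of the daily curve is exactly what identifies an
  hour-specific coefficient; with a perfectly repeating diurnal cycle the FD
  model would be unidentifiable, which real hourly weather is not.

What the generator does **not** emulate: spatial averaging of stations,
measurement gaps, influenza epidemics, heat-wave harvesting dynamics, or any
non-Poisson overdispersion. Passing recovery tests on these data therefore
show that the estimators are implemented correctly and are consistent under
their own assumptions — not that the assumptions hold for any particular
city's data.

## The benchmark DLNM and the AG strategy

The cross-basis uses quadratic B-splines in the temperature dimension with
knots at the 10th, 75th and 90th percentiles of the observed series (type-7
quantiles, boundary knots at the observed extremes) and natural cubic
splines over lags 0–21 with three interior knots equally spaced on the
`log(lag + 1)` scale. The var-dimension basis drops its partition-of-unity
column, otherwise each lag-basis block would sum to a constant and collide
with the intercept. Long-term trend is a natural spline with one degree of
freedom per decade (minimum one) and seasonality four sine/cosine pairs on
day-of-year over 365.25. The model is fitted by quasi-Poisson IRLS
(convergence 1e-10, dispersion = Pearson χ²/df), which keeps the log link
and relative-risk interpretation while admitting the non-integer aggregated
response of the AG strategy. The first 21 days, whose lag history is
incomplete, are excluded from the likelihood rather than imputed.

The overall cumulative relative-risk curve contrasts a sustained exposure at
each grid temperature with a reference, with delta-method bands; by default
the reference is the minimum-mortality temperature within the central 99% of
observed temperatures.

For AG, the window is interpreted as the current day plus six future days
(weights `1 - (k/W)^2`, `k = 0..W-1`, renormalised over available days at
the series tail), so the weighting is strictly null on the left and a window
of 7 matches the weekly confounding scale. With `window = 1` the strategy
*is* the benchmark, bit for bit — a useful identity test. The AR model for
the aggregation-induced autocorrelation is fitted sequentially on
Pearson-scale residuals `(y - mu)/sqrt(mu)` by conditional least squares,
with the order chosen by a forward stepwise search that stops at the first
AIC increase (ties toward the smaller order). The residual scale is a
package decision — the sequential two-stage structure admits several; the
Pearson scale makes the AR variance roughly constant across the seasonal
cycle.

## EMDR: decomposition choices

The multivariate EMD projects the (temperature + 2 noise channels) signal
onto 64 direction vectors placed quasi-uniformly on the unit sphere
(Halton points mapped through the normal quantile and normalised — a
Hammersley-style low-discrepancy construction that works for any channel
count). For each direction, envelopes interpolate all channels at the
extrema of the projection with natural cubic splines, mirror-extended at the
boundaries; the sifting criterion is Rilling's (amplitude ratio below 0.05
on 95% of points and below 0.5 everywhere, at most 100 iterations). The
mean envelope averages `(upper + lower)/2` over directions rather than
maxima-only envelopes over a sign-symmetric direction set — equivalent in
expectation and half the directions for the same accuracy. Because spline
interpolation is linear in the data, the projection amplitude needed by the
stopping rule is obtained by projecting the channel envelopes, with no
extra spline fits.

The noise channels (two, sd = 20% of the temperature sd, seeded) prevent
mode mixing but make the per-channel modes "rotational": the temperature
channel of a multivariate IMF need not satisfy the univariate IMF property.
A cheap univariate cleanup pass therefore sifts each kept IMF until its
extremum and zero-crossing counts differ by at most one, cascading the
removed part into the next mode, so the reconstruction identity
`sum(IMFs) + residual = signal` is preserved exactly. Components with fewer
than two zero crossings are folded into the residual trend.

The regression step standardises the IMFs plus the residual trend and runs
the Poisson Lasso path (100 log-spaced penalties down to `1e-4 * lambda_max`,
warm starts, unpenalized intercept) with the penalty minimising 10-fold
cross-validated deviance over seeded random day folds. No additional trend
or seasonality controls enter: the IMFs and residual *are* the trend and
seasonality. Confidence intervals come from an unpenalized refit on the
selected support and are therefore post-selection approximations; relative
risks are reported per interquartile-range increase of each component so
that risks are comparable across frequency bands (the amplitude scaling of
a per-IMF risk is otherwise undefined).

## Functional strategies: boosting choices

Both functional models are fitted by component-wise gradient boosting with
Poisson loss, step 0.1, and at most 100 iterations, with the stopping
iteration chosen by seeded 10-fold cross-validation (years for FY, days for
FD) — the only randomness in either fit. Base learners are penalized
least-squares smoothers whose ridge amount is calibrated so the smoother
trace equals the target effective degrees of freedom (to 1e-6, by solving
the eigenvalue form with `uniroot`). One numerical point deserves note: the
raw Poisson gradient `y - exp(f)` lives on the response scale, so with a
fixed step its magnitude — and the stability of the iteration — depends on
the count level. The gradient is therefore scaled by the constant baseline
Fisher weight `exp(f0)`; the stationary point is unchanged, the Gaussian
case is untouched, and training loss is non-increasing for any count level
(asserted on every run).

**FY.** `log mu_y(t) = alpha + trend(y) + sum_{s=0..30} beta(s,t) x_y(t-s)`
on the 365-day grid (Feb 29 removed so all years share the grid; it is kept
in all daily-scale analyses). The exposure history crosses into the
previous year's tail, so winter days keep their full 30-day window; only
the first year's first 30 days are excluded from the loss. The coefficient
surface is a tensor-product cubic P-spline (8 equispaced interior knots and
a second-order difference penalty per margin) with a single ridge parameter
calibrated to 4 × 4 = 16 effective degrees of freedom ("4 df on both
margins"); the inter-annual trend is an unpenalized 3-df natural spline over
the year index. The day-of-year margin is not made cyclic: the boundary
days' histories already tie the years together through the data. The
cumulative curve `exp(sum_s beta(s,t))` is the risk of a +1 °C deviation
sustained over the whole window, as a function of when in the year it
occurs.

**FD.** `log mu_t = alpha + trend(t) + dow(t) + (1/24) sum_h beta(h)
x_{t-1}(h)`, with `beta(h)` a cubic P-spline with exactly 2 interior knots
(6 basis functions, 4 effective df — the analogue of the FY margins, since
only the knot count is pinned by the model design). The smooth time
learner is a P-spline over the day index with knots every ~6 months and a
3-df target, capturing the inter-annual mortality trend only — seasonality
is deliberately not modelled separately, since the FD estimand is a
sub-daily profile and its evaluation is restricted to summer; day-of-week
enters unpenalized (treatment coding). The hourly integral is discretized as the mean over 24
points, so `beta(h)` is a log-rate change per °C sustained for a day. The
model is fitted to all days with a previous-day hourly curve; the
evaluation harness restricts FD *scoring* to June–August, where a sub-daily
heat signal is the target, but the fit itself uses all seasons.

Neither boosting fit has analytic intervals, so the 95% bands of the FY
cumulative curve and the FD hourly curve come from a nonparametric
bootstrap over observational units (years for FY; 7-day blocks for FD),
refitting at the selected stopping iteration, 100 resamples by default.
These are approximate and do not account for the selection of `mstop`.

## The comparison harness

Strategies are compared by leave-one-year-out hv-block cross-validation:
each complete year in turn is the validation block and a guard margin equal
to the strategy's maximum lag (21 days for DLNM/AG, 30 for FY, 1 for FD, 0
for EMDR) is excised from training on both sides, eliminating dependence
leakage through lagged exposures. All strategies are scored against the
*raw* daily counts — the AG model predicts an aggregated series, and its
expectation is used directly as the raw-scale prediction, a package
decision that keeps the comparison on one scale. EMDR is the one strategy
whose transform cannot be made out-of-sample: empirical mode decomposition
is non-causal, so each fold reuses IMF values from a decomposition of the
full exposure series and only the regression is refitted. This shortcut is
mildly optimistic for EMDR and is flagged in the `compare_strategies()`
documentation.

The error measure is the day-of-year relative RMSE: for each day-of-year,
the RMSE of predictions across validation years divided by the mean
observed count on that day (Feb 29 merged into day 59). The raw curves are
smoothed by locally weighted regression (tricube weights, local linear,
span 0.15) with *circular* distance so Dec 31 neighbours Jan 1; an ordinary
LOESS would leave a seam at the year boundary.

## Problem sizes and numerical conventions

The test-suite exercises the full pipeline at the study scale where the
property being checked needs it (31-year EMD reconstruction, DLNM recovery
at n = 11,322, FD at n = 1,826) and at 4–10 synthetic years where it does
not (harness consistency, oracle dominance); `scripts/acceptance.R` states
the size it used for every quantity it reports. Other conventions: type-7
quantiles everywhere; IRLS convergence 1e-10; Lasso convergence 1e-10;
df calibration 1e-6; ties in the AR order search and the Lasso path follow
the smaller-model side; degenerate inputs (constant series, too few
extrema, rank-deficient designs) raise errors rather than returning silent
results — with one exception: a base learner whose design cannot support
the requested df (e.g. perfectly flat daily curves in FD) falls back to the
weakest penalty instead of failing, because that degeneracy is data- not
user-caused.

## Known limitations

All four strategies are linear in the (transformed) exposure; none models
interactions between scales; the EMDR intervals ignore selection; the FY
surface is estimated from as many functional observations as there are
years, so at 31 years it is heavily regularised; and the harness's EMDR
shortcut described above means its cross-validated error is a lower bound.

One consequence of the fixed boosting budget deserves emphasis: with step
0.1 and at most 100 iterations shared among the learners, the ridge-type
base learners' high-curvature directions (smoother eigenvalues well below
one) are only partially converged when the iteration cap binds — and the
cross-validated stopping rule regularly *asks* for the cap, i.e. more
iterations would be chosen if allowed. For the FD model this attenuates and
mildly distorts the curvature of the fitted hourly coefficient even on
noise-free data (simulations in the test-suite put the shape correlation
ceiling near 0.89 for a sinusoidal truth; the same model run to 300
iterations, or an unpenalized GLM on the same design, recovers the shape
essentially exactly). Users fitting FD models to strong sub-daily signals
should inspect whether `fit$boost$mstop` equals `mstop_max` and consider
raising `fd$mstop_max` in [run_config()] beyond the conventional 100.
The CLI (`inst/cli/wxmort.R`) is a thin wrapper over the exported functions
and adds no behaviour of its own.
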
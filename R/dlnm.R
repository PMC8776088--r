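## Benchmark distributed lag non-linear model: cross-basis construction,
## quasi-Poisson fit with long-term trend and seasonal controls, and overall
## cumulative relative-risk curves with delta-method intervals.

#' B-spline design matrix
#'
#' Thin wrapper building the standard B-spline basis (including the
#' partition-of-unity intercept column) for given interior knots, degree and
#' boundary knots.
#'
#' @param x evaluation points, inside the boundary.
#' @param knots interior knots, strictly increasing, inside the boundary.
#' @param degree spline degree (2 = quadratic).
#' @param boundary length-2 boundary knots enclosing `knots` and `x`.
#' @return A matrix with `length(knots) + degree + 1` columns whose rows sum
#'   to one.
#' @export
bspline_design <- function(x, knots, degree = 2L, boundary = range(x)) {
  if (length(knots) && any(diff(knots) <= 0))
    stop("interior knots must be strictly increasing")
  if (length(knots) && (min(knots) <= boundary[1L] || max(knots) >= boundary[2L]))
    stop("interior knots must lie strictly inside the boundary")
  if (any(x < boundary[1L] - 1e-8) || any(x > boundary[2L] + 1e-8))
    stop("'x' outside the boundary knots")
  x <- pmin(pmax(x, boundary[1L]), boundary[2L])
  ord <- degree + 1L
  kv <- c(rep(boundary[1L], ord), knots, rep(boundary[2L], ord))
  splines::splineDesign(kv, x, ord = ord)
}

## Natural cubic lag basis with interior knots equally spaced on the
## log(lag + 1) scale, intercept included.
lag_basis <- function(max_lag, n_knots = 3L) {
  lags <- 0:max_lag
  if (max_lag == 0L) return(matrix(1, 1L, 1L))
  kn <- expm1(seq(0, log1p(max_lag), length.out = n_knots + 2L))[-c(1L, n_knots + 2L)]
  splines::ns(lags, knots = kn, Boundary.knots = c(0, max_lag), intercept = TRUE)
}

#' Cross-basis of a temperature series
#'
#' Builds the lag-by-temperature tensor-product design of a distributed lag
#' non-linear model: quadratic B-splines in the temperature dimension with
#' knots at configured quantiles of the observed series (type-7 quantiles,
#' boundary at the observed min/max), natural cubic splines in the lag
#' dimension with knots equally spaced on the log-lag scale, summed over
#' lags `0..max_lag` for each day. The first `max_lag` rows have incomplete
#' lag histories and are flagged for exclusion from fitting.
#'
#' @param temp a temperature [daily_series()] or numeric vector.
#' @param cfg a [run_config()]; uses the `dlnm` block.
#' @param var_knots,var_boundary optional fixed temperature knots/boundary
#'   (used when predicting from a fitted model).
#' @return A list of class `cross_basis`: `Q` (design matrix), `complete`
#'   (logical rows), `var_knots`, `var_boundary`, `var_degree`, `B_lag`
#'   (lag basis matrix) and `max_lag`.
#' @export
build_cross_basis <- function(temp, cfg = run_config(), var_knots = NULL,
                              var_boundary = NULL) {
  x <- if (inherits(temp, "daily_series")) temp$value else as.numeric(temp)
  dc <- cfg$dlnm
  L <- dc$max_lag
  n <- length(x)
  if (n <= L) stop("series must be longer than the maximum lag")
  if (is.null(var_knots))
    var_knots <- unname(quantile(x, dc$var_knot_probs, type = 7))
  if (is.null(var_boundary)) var_boundary <- range(x)
  # drop the partition-of-unity column: with it, each lag-basis block would
  # sum to a constant and collide with the model intercept
  V <- bspline_design(x, var_knots, dc$var_degree, var_boundary)[, -1L, drop = FALSE]
  B <- lag_basis(L, dc$n_lag_knots)
  nv <- ncol(V); nl <- ncol(B)
  Q <- matrix(0, n, nv * nl)
  for (l in 0:L) {
    rows <- (l + 1L):n
    contrib <- V[rows - l, rep(seq_len(nv), each = nl), drop = FALSE]
    bl <- B[l + 1L, rep(seq_len(nl), times = nv)]
    Q[rows, ] <- Q[rows, ] + sweep(contrib, 2L, bl, "*")
  }
  complete <- c(rep(FALSE, min(L, n)), rep(TRUE, max(n - L, 0L)))
  structure(list(Q = Q, complete = complete, var_knots = var_knots,
                 var_boundary = var_boundary, var_degree = dc$var_degree,
                 B_lag = unclass(B)[, , drop = FALSE], max_lag = L),
            class = "cross_basis")
}

#' Seasonal harmonic control columns
#'
#' `sin(2*pi*k*doy/365.25)` and `cos(2*pi*k*doy/365.25)` for
#' `k = 1..pairs`, evaluated at each date's day of year.
#'
#' @param dates `Date` vector.
#' @param pairs number of sine/cosine pairs.
#' @return A matrix with `2 * pairs` columns.
#' @export
seasonal_harmonics <- function(dates, pairs = 4L) {
  doy <- as.POSIXlt(dates)$yday + 1L
  out <- matrix(0, length(dates), 2L * pairs)
  for (k in seq_len(pairs)) {
    ang <- 2 * pi * k * doy / 365.25
    out[, 2L * k - 1L] <- sin(ang)
    out[, 2L * k] <- cos(ang)
  }
  colnames(out) <- paste0(rep(c("sin", "cos"), pairs),
                          rep(seq_len(pairs), each = 2L))
  out
}

#' Long-term trend spline basis
#'
#' Natural cubic spline over the time index with roughly one degree of
#' freedom per decade (never fewer than one).
#'
#' @param dates `Date` vector spanning at least one year.
#' @param df_per_decade degrees of freedom per decade of span.
#' @return A basis matrix with attributes `knots`, `boundary` and `origin`
#'   so it can be re-evaluated at new dates via [trend_spline_predict()].
#' @export
trend_spline <- function(dates, df_per_decade = 1) {
  idx <- as.numeric(dates - dates[1L]) + 1
  df <- max(1L, as.integer(round(length(dates) / 3652.5 * df_per_decade)))
  basis <- splines::ns(idx, df = df)
  structure(unclass(basis)[, , drop = FALSE],
            knots = attr(basis, "knots"),
            boundary = attr(basis, "Boundary.knots"),
            origin = dates[1L], df = df)
}

#' @rdname trend_spline
#' @param basis a basis returned by [trend_spline()].
#' @param dates new dates (extrapolation beyond the training span is linear,
#'   the natural-spline boundary behaviour).
#' @export
trend_spline_predict <- function(basis, dates) {
  idx <- as.numeric(dates - attr(basis, "origin")) + 1
  unclass(splines::ns(idx, knots = attr(basis, "knots"),
                      Boundary.knots = attr(basis, "boundary")))[, , drop = FALSE]
}

#' Quasi-Poisson fit by iteratively reweighted least squares
#'
#' Log-link fit with the Poisson variance function and a free dispersion,
#' so aggregated (non-integer) responses are admitted. Convergence is to a
#' relative deviance change below 1e-10; the dispersion is the Pearson
#' statistic over the residual degrees of freedom and the coefficient
#' covariance is `dispersion * (X'WX)^{-1}`.
#'
#' @param y non-negative response.
#' @param X full-rank design matrix (including the intercept column).
#' @return A list with `coefficients`, `vcov`, `dispersion`, `fitted`,
#'   `converged`.
#' @export
fit_quasipoisson <- function(y, X) {
  X <- as.matrix(X)
  if (any(y < 0)) stop("negative response")
  fit <- glm.fit(X, y, family = quasipoisson(),
                 control = list(epsilon = 1e-10, maxit = 100L))
  if (!fit$converged) stop("IRLS did not converge in 100 iterations")
  if (fit$rank < ncol(X)) stop("design matrix is rank deficient")
  mu <- fit$fitted.values
  rdf <- length(y) - ncol(X)
  dispersion <- sum((y - mu)^2 / mu) / rdf
  XtWX <- crossprod(X * sqrt(fit$weights))
  vc <- dispersion * chol2inv(chol(XtWX))
  list(coefficients = fit$coefficients, vcov = vc, dispersion = dispersion,
       fitted = mu, converged = fit$converged)
}

#' Fit the benchmark distributed lag non-linear model
#'
#' Quasi-Poisson regression of daily (or aggregated) deaths on the
#' temperature cross-basis, a long-term trend spline (one df per decade)
#' and four seasonal sine/cosine pairs. Days with incomplete lag histories
#' are excluded from the likelihood.
#'
#' @param resp a count or aggregated [daily_series()].
#' @param temp a temperature [daily_series()] on the same dates.
#' @param cfg a [run_config()].
#' @return An object of class `dlnm_fit`.
#' @export
fit_dlnm <- function(resp, temp, cfg = run_config()) {
  stopifnot(inherits(resp, "daily_series"), inherits(temp, "daily_series"))
  if (!identical(resp$date, temp$date)) stop("series must share their dates")
  cb <- build_cross_basis(temp, cfg)
  tr <- trend_spline(resp$date, cfg$dlnm$trend_df_per_decade)
  se <- seasonal_harmonics(resp$date, cfg$dlnm$seasonal_pairs)
  X <- cbind(1, cb$Q, tr, se)
  blocks <- list(intercept = 1L,
                 cb = 1L + seq_len(ncol(cb$Q)),
                 trend = 1L + ncol(cb$Q) + seq_len(ncol(tr)),
                 seasonal = 1L + ncol(cb$Q) + ncol(tr) + seq_len(ncol(se)))
  ok <- cb$complete
  qp <- fit_quasipoisson(resp$value[ok], X[ok, , drop = FALSE])
  structure(list(coefficients = qp$coefficients, vcov = qp$vcov,
                 dispersion = qp$dispersion, blocks = blocks,
                 cb = cb[setdiff(names(cb), "Q")], trend = tr,
                 fitted_values = qp$fitted, complete = ok,
                 dates = resp$date, temp_range = range(temp$value),
                 cfg = cfg, y = resp$value),
            class = "dlnm_fit")
}

#' @export
print.dlnm_fit <- function(x, ...) {
  cat(sprintf("<dlnm_fit: %d days fitted, dispersion %.3f>\n",
              sum(x$complete), x$dispersion))
  cat(sprintf("  cross-basis %d columns (lag 0..%d), trend df %d, %d harmonic columns\n",
              length(x$blocks$cb), x$cb$max_lag, attr(x$trend, "df"),
              length(x$blocks$seasonal)))
  invisible(x)
}

#' @export
coef.dlnm_fit <- function(object, ...) object$coefficients

#' @export
vcov.dlnm_fit <- function(object, ...) object$vcov

#' @export
fitted.dlnm_fit <- function(object, ...) object$fitted_values

#' @export
summary.dlnm_fit <- function(object, ...) {
  rr <- overall_cumulative_rr(object)
  out <- list(fit = object, rr = rr)
  class(out) <- "summary.dlnm_fit"
  out
}

#' @export
print.summary.dlnm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  minimum-risk reference %.1f degC; RR at grid ends: %.2f (cold), %.2f (heat)\n",
              attr(x$rr, "reference"), x$rr$rr[1L], x$rr$rr[nrow(x$rr)]))
  invisible(x)
}

#' Predict expected counts from a fitted DLNM
#'
#' @param object a `dlnm_fit`.
#' @param newdata optional list with element `temp` (a temperature
#'   [daily_series()] whose first `max_lag` days serve as lag history).
#'   When omitted, in-sample fitted values are returned.
#' @param ... unused.
#' @return A data frame with `date` and predicted expectation `mu` (days
#'   with a complete lag history only).
#' @export
predict.dlnm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(data.frame(date = object$dates[object$complete],
                      mu = object$fitted_values))
  temp <- newdata$temp
  stopifnot(inherits(temp, "daily_series"))
  cb <- build_cross_basis(temp, object$cfg,
                          var_knots = object$cb$var_knots,
                          var_boundary = clamp_boundary(object$cb$var_boundary, temp$value))
  tr <- trend_spline_predict(object$trend, temp$date)
  se <- seasonal_harmonics(temp$date, object$cfg$dlnm$seasonal_pairs)
  X <- cbind(1, cb$Q, tr, se)
  ok <- cb$complete
  eta <- drop(X[ok, , drop = FALSE] %*% object$coefficients)
  data.frame(date = temp$date[ok], mu = exp(eta))
}

## widen a stored boundary so prediction temperatures stay inside it
clamp_boundary <- function(boundary, x) {
  c(min(boundary[1L], min(x)), max(boundary[2L], max(x)))
}

#' Overall cumulative relative-risk curve
#'
#' Sums the fitted lag-specific effects over the whole lag window at each
#' grid temperature and contrasts against a reference temperature, giving
#' the relative risk of a sustained exposure. Pointwise 95% intervals come
#' from the delta method. The default reference is the minimum-mortality
#' temperature: the argmin of the fitted curve within the central 99% of
#' observed temperatures.
#'
#' @param fit a `dlnm_fit` or `ag_fit`.
#' @param grid temperature grid; defaults to 100 points over the observed
#'   range.
#' @param reference numeric reference temperature, or `"mmt"`.
#' @param ... passed to methods.
#' @return An object of class `rr_curve`: data frame with `temp`, `rr`,
#'   `lo95`, `hi95` and attribute `reference`.
#' @export
overall_cumulative_rr <- function(fit, grid = NULL, reference = "mmt", ...) {
  UseMethod("overall_cumulative_rr")
}

#' @rdname overall_cumulative_rr
#' @export
overall_cumulative_rr.dlnm_fit <- function(fit, grid = NULL,
                                           reference = "mmt", ...) {
  if (is.null(grid))
    grid <- seq(fit$temp_range[1L], fit$temp_range[2L], length.out = 100L)
  if (any(grid < fit$temp_range[1L] - 1e-8) ||
      any(grid > fit$temp_range[2L] + 1e-8))
    stop("grid outside the observed temperature range")
  beta <- fit$coefficients[fit$blocks$cb]
  V <- fit$vcov[fit$blocks$cb, fit$blocks$cb, drop = FALSE]
  lag_sums <- colSums(fit$cb$B_lag)
  cvec <- function(x) {
    v <- bspline_design(x, fit$cb$var_knots, fit$cb$var_degree,
                        fit$cb$var_boundary)[, -1L, drop = FALSE]
    # column order matches build_cross_basis: var-major, lag within
    as.vector(t(outer(drop(v), lag_sums)))
  }
  C <- t(vapply(grid, cvec, numeric(length(beta))))
  if (identical(reference, "mmt")) {
    logrr0 <- drop(C %*% beta)
    central <- quantile(grid, c(0.005, 0.995), type = 7)
    ok <- grid >= central[1L] & grid <= central[2L]
    reference <- grid[ok][which.min(logrr0[ok])]
  }
  if (reference < fit$temp_range[1L] || reference > fit$temp_range[2L])
    stop("reference outside the observed temperature range")
  Cd <- sweep(C, 2L, cvec(reference), "-")
  logrr <- drop(Cd %*% beta)
  se <- sqrt(pmax(rowSums((Cd %*% V) * Cd), 0))
  out <- data.frame(temp = grid, rr = exp(logrr),
                    lo95 = exp(logrr - 1.96 * se),
                    hi95 = exp(logrr + 1.96 * se))
  structure(out, reference = reference,
            class = c("rr_curve", "data.frame"))
}

#' @export
print.rr_curve <- function(x, ...) {
  cat(sprintf("<rr_curve: %d grid points, reference %.2f degC>\n",
              nrow(x), attr(x, "reference")))
  print.data.frame(head(as.data.frame(x), 4L))
  cat("  ...\n")
  invisible(x)
}

#' @export
plot.rr_curve <- function(x, ...) {
  graphics::plot(x$temp, x$rr, type = "l", log = "y",
                 xlab = "temperature (degC)", ylab = "relative risk", ...)
  graphics::lines(x$temp, x$lo95, lty = 2)
  graphics::lines(x$temp, x$hi95, lty = 2)
  graphics::abline(h = 1, col = "grey")
  graphics::abline(v = attr(x, "reference"), col = "grey", lty = 3)
  invisible(x)
}
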
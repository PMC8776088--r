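#' Causal (one-sided) Epanechnikov kernel aggregation
#'
#' Smooths a daily count series using only the current and future values:
#' the value at day `t` is the weighted mean of days `t .. t+W-1` with
#' Epanechnikov weights `w_k` proportional to `1 - (k/W)^2`, normalised to
#' sum to one. Near the end of the series the weights are renormalised over
#' the available days, so the last observation equals itself. This smooths
#' short-term confounding such as day-of-week patterns while preserving the
#' location of mortality episodes.
#'
#' @param s a count [daily_series()].
#' @param window window size `W` in days (`W = 1` is the identity).
#' @return An aggregated [daily_series()].
#' @export
causal_kernel_smooth <- function(s, window = 7L) {
  stopifnot(inherits(s, "daily_series"))
  window <- as.integer(window)
  if (window < 1L) stop("'window' must be at least 1")
  n <- nrow(s)
  if (window >= n) stop("'window' must be smaller than the series length")
  w <- epanechnikov_weights(window)
  num <- rep(0, n)
  den <- rep(0, n)
  for (k in seq_len(window) - 1L) {
    idx <- seq_len(n - k)
    num[idx] <- num[idx] + w[k + 1L] * s$value[idx + k]
    den[idx] <- den[idx] + w[k + 1L]
  }
  daily_series(s$date, num / den, "aggregated")
}

## One-sided Epanechnikov weights on support k = 0..W-1, summing to 1
epanechnikov_weights <- function(window) {
  k <- seq_len(window) - 1L
  w <- 1 - (k / window)^2
  w / sum(w)
}

#' Fit an autoregressive model with forward stepwise AIC order selection
#'
#' Orders are explored from 0 upwards by conditional least squares (each
#' candidate regresses the series on its own lags, conditioning on the first
#' `p_max` observations so AICs are comparable), stopping at the first order
#' whose AIC increases; ties are broken toward the smaller order.
#'
#' @param residuals numeric vector, length greater than `10 * p_max`.
#' @param p_max maximum order to consider.
#' @return An object of class `ar_fit` with fields `order`, `coefficients`,
#'   `innovation_variance`, `aic` (the selected order's AIC) and
#'   `aic_path`.
#' @export
fit_ar_by_aic <- function(residuals, p_max = 5L) {
  x <- as.numeric(residuals)
  p_max <- as.integer(p_max)
  n <- length(x)
  if (n <= 10L * max(p_max, 1L)) stop("series too short for AR fitting")
  if (var(x) == 0) stop("constant residual vector: AR model undefined")
  n_eff <- n - p_max
  y <- x[(p_max + 1L):n]
  aic_of <- function(p) {
    if (p == 0L) {
      rss <- sum((y - mean(y))^2)
      list(aic = n_eff * log(rss / n_eff) + 2 * 1, coef = numeric(0L),
           sigma2 = rss / n_eff)
    } else {
      X <- cbind(1, vapply(seq_len(p), function(l)
        x[(p_max + 1L - l):(n - l)], numeric(n_eff)))
      fit <- lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      list(aic = n_eff * log(rss / n_eff) + 2 * (p + 1),
           coef = fit$coefficients[-1L], sigma2 = rss / n_eff)
    }
  }
  best <- aic_of(0L)
  best_p <- 0L
  path <- setNames(best$aic, "0")
  p <- 0L
  while (p < p_max) {
    p <- p + 1L
    cand <- aic_of(p)
    path <- c(path, setNames(cand$aic, as.character(p)))
    if (cand$aic < best$aic) {
      best <- cand
      best_p <- p
    } else break  # first AIC increase stops the stepwise search
  }
  structure(list(order = best_p,
                 coefficients = unname(best$coef),
                 innovation_variance = best$sigma2,
                 aic = best$aic, aic_path = path),
            class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("<ar_fit: AR(%d), innovation variance %.4g, AIC %.2f>\n",
              x$order, x$innovation_variance, x$aic))
  if (x$order > 0L)
    cat("  coefficients:", paste(sprintf("%.4f", x$coefficients),
                                 collapse = ", "), "\n")
  invisible(x)
}

## Spectral radius of the AR companion matrix; < 1 means stationary
ar_spectral_radius <- function(fit) {
  p <- fit$order
  if (p == 0L) return(0)
  comp <- rbind(fit$coefficients,
                cbind(diag(1, p - 1L, p - 1L), rep(0, p - 1L)))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Fit the aggregation strategy
#'
#' Aggregates the mortality response with [causal_kernel_smooth()], fits the
#' benchmark distributed lag non-linear model to the aggregated response by
#' quasi-likelihood (the log link and Poisson variance function are kept, so
#' relative risks retain their interpretation for the non-integer response),
#' and models the remaining autocorrelation of the Pearson-scale residuals
#' with an AIC-selected AR process. The two components are fitted
#' sequentially, not jointly.
#'
#' @param mort a count [daily_series()].
#' @param temp a temperature [daily_series()] on the same dates.
#' @param cfg a [run_config()].
#' @param window aggregation window, defaulting to `cfg$ag$window`.
#' @return An object of class `ag_fit` wrapping the [fit_dlnm()] result
#'   (`$dlnm`), the [fit_ar_by_aic()] result (`$ar`) and the aggregated
#'   series (`$aggregated`).
#' @export
run_ag <- function(mort, temp, cfg = run_config(), window = NULL) {
  stopifnot(inherits(mort, "daily_series"), inherits(temp, "daily_series"))
  if (!identical(mort$date, temp$date)) stop("series must share their dates")
  if (is.null(window)) window <- cfg$ag$window
  agg <- causal_kernel_smooth(mort, window)
  dl <- fit_dlnm(agg, temp, cfg)
  mu <- fitted(dl)
  pearson <- (agg$value[dl$complete] - mu) / sqrt(mu)
  ar <- fit_ar_by_aic(pearson, cfg$ag$p_max)
  structure(list(dlnm = dl, ar = ar, aggregated = agg, window = window),
            class = "ag_fit")
}

#' @export
print.ag_fit <- function(x, ...) {
  cat(sprintf("<ag_fit: window %d days>\n", x$window))
  print(x$dlnm)
  print(x$ar)
  invisible(x)
}

#' @export
coef.ag_fit <- function(object, ...) coef(object$dlnm)

#' @export
predict.ag_fit <- function(object, newdata = NULL, ...) {
  predict(object$dlnm, newdata = newdata, ...)
}

#' @rdname overall_cumulative_rr
#' @export
overall_cumulative_rr.ag_fit <- function(fit, grid = NULL, reference = "mmt", ...) {
  overall_cumulative_rr(fit$dlnm, grid = grid, reference = reference, ...)
}
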
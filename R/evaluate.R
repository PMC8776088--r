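## Comparison harness: leave-one-year-out hv-block cross-validation,
## day-of-year relative RMSE curves, and circular LOESS smoothing.

#' hv-block cross-validation folds by calendar year
#'
#' One fold per complete calendar year: the year is the validation block
#' and the training set is everything else minus a guard margin of
#' `guard_days` on each side of the block, which removes serial dependence
#' between training and validation.
#'
#' @param dates contiguous `Date` vector.
#' @param guard_days guard margin (days) excised on each side.
#' @return A list of folds, each with `year`, `val` (logical over `dates`)
#'   and `train` (logical).
#' @export
hv_folds <- function(dates, guard_days = 0L) {
  yr <- as.integer(format(dates, "%Y"))
  complete <- Filter(function(y)
    sum(yr == y) == days_in_span(sprintf("%d-01-01", y), sprintf("%d-12-31", y)),
    unique(yr))
  if (length(complete) < 2L) stop("need at least 2 complete years")
  lapply(complete, function(y) {
    val <- yr == y
    lo <- min(dates[val]) - guard_days
    hi <- max(dates[val]) + guard_days
    train <- !(dates >= lo & dates <= hi)
    list(year = y, val = val, train = train)
  })
}

#' Relative RMSE by day of year
#'
#' For each day-of-year the root mean squared prediction error across years
#' is divided by that day's mean observed count. Feb 29 is merged into day
#' 59. Days with predictions in no year, or a zero mean count, yield `NA`.
#'
#' @param pred numeric vector of predicted expected counts aligned with
#'   `obs` (`NA` where no prediction).
#' @param obs observed count [daily_series()].
#' @return A numeric vector of length 365.
#' @export
rrmse_by_doy <- function(pred, obs) {
  stopifnot(inherits(obs, "daily_series"))
  if (inherits(pred, "daily_series")) pred <- pred$value
  if (length(pred) != nrow(obs)) stop("'pred' must align with 'obs'")
  doy <- doy365(obs$date)
  out <- rep(NA_real_, 365L)
  for (d in 1:365) {
    i <- which(doy == d & !is.na(pred))
    if (!length(i)) next
    denom <- mean(obs$value[i])
    if (denom == 0) next
    out[d] <- sqrt(mean((pred[i] - obs$value[i])^2)) / denom
  }
  out
}

#' Circular LOESS smoothing of a day-of-year curve
#'
#' Local linear regression with tricube weights over the `span` fraction of
#' nearest neighbours, with distance measured around the calendar circle
#' (Dec 31 adjacent to Jan 1) unless `circular = FALSE`. `NA` entries are
#' omitted from the local fits and remain `NA` in the output where no
#' window data exist.
#'
#' @param curve numeric vector of length 365.
#' @param span fraction of points in each local window, in (0, 1].
#' @param circular use circular day-of-year distance.
#' @return Smoothed numeric vector of length 365.
#' @export
loess_smooth <- function(curve, span = 0.15, circular = TRUE) {
  n <- length(curve)
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  k <- max(3L, ceiling(span * n))
  if (sum(!is.na(curve)) < 3L) stop("too few non-missing points")
  out <- rep(NA_real_, n)
  idx <- seq_len(n)
  for (d in idx) {
    delta <- idx - d
    if (circular) {
      delta <- ((delta + n / 2) %% n) - n / 2
    }
    ok <- !is.na(curve)
    ord <- order(abs(delta))
    take <- ord[ok[ord]][seq_len(min(k, sum(ok)))]
    if (length(take) < 3L) next
    x <- delta[take]
    w <- (1 - (abs(x) / (max(abs(x)) + 1e-9))^3)^3
    # weighted local linear fit evaluated at the centre (x = 0)
    sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
    sy <- sum(w * curve[take]); sxy <- sum(w * x * curve[take])
    det <- sw * sxx - sx^2
    out[d] <- if (abs(det) < 1e-12) sy / sw else (sxx * sy - sx * sxy) / det
  }
  out
}

#' Compare strategies by hv-block cross-validation
#'
#' Runs each requested strategy with one fold per complete year (see
#' [hv_folds()]; the guard margin equals the strategy's maximum lag: 21
#' days for the DLNM and AG, 30 for FY, 1 for FD, 0 for EMDR), predicts the
#' held-out year's expected counts on the raw daily scale, and assembles
#' day-of-year relative RMSE curves, raw and LOESS-smoothed. The FD
#' strategy is evaluated on June-August only. An `"oracle"` strategy
#' (predicting the true expectation, available for simulated data via
#' `mu`) provides a lower-bound reference.
#'
#' EMDR uses IMFs from a decomposition of the full exposure series in every
#' fold (only the regression is refitted); empirical mode decomposition is
#' not causal, so a strictly out-of-sample decomposition is undefined and
#' this shortcut is mildly optimistic for EMDR.
#'
#' @param mort a count [daily_series()].
#' @param temp a temperature [daily_series()] on the same dates.
#' @param hourly an [hourly_series()] (required for `"fd"`).
#' @param strategies character subset of
#'   `c("dlnm", "ag", "emdr", "fy", "fd", "oracle")`.
#' @param cfg a [run_config()].
#' @param mu true expected counts (for `"oracle"`).
#' @return An object of class `cv_report`: `rrmse_raw` and `rrmse_smooth`
#'   (strategy x 365 matrices), `predictions` (strategy x days), and a fold
#'   log.
#' @export
compare_strategies <- function(mort, temp, hourly = NULL,
                               strategies = c("dlnm", "ag", "emdr", "fy"),
                               cfg = run_config(), mu = NULL) {
  stopifnot(inherits(mort, "daily_series"), inherits(temp, "daily_series"))
  known <- c("dlnm", "ag", "emdr", "fy", "fd", "oracle")
  strategies <- match.arg(strategies, known, several.ok = TRUE)
  guards <- c(dlnm = 21L, ag = 21L, emdr = 0L, fy = 30L, fd = 1L, oracle = 0L)
  preds <- matrix(NA_real_, length(strategies), nrow(mort),
                  dimnames = list(strategies, NULL))
  fold_log <- list()
  for (s in strategies) {
    if (s == "fd" && is.null(hourly)) {
      warning("strategy 'fd' skipped: no hourly series supplied")
      next
    }
    if (s == "oracle" && is.null(mu)) {
      warning("strategy 'oracle' skipped: no true expectation supplied")
      next
    }
    folds <- hv_folds(mort$date, guards[[s]])
    fold_log[[s]] <- data.frame(
      year = vapply(folds, `[[`, integer(1L), "year"),
      n_train = vapply(folds, function(f) sum(f$train), integer(1L)),
      guard = guards[[s]])
    preds[s, ] <- switch(s,
      dlnm = cv_predict_dlnm(mort, temp, cfg, folds, window = 1L),
      ag = cv_predict_dlnm(mort, temp, cfg, folds, window = cfg$ag$window),
      emdr = cv_predict_emdr(mort, temp, cfg, folds),
      fy = cv_predict_fy(mort, temp, cfg, folds),
      fd = cv_predict_fd(mort, hourly, cfg, folds),
      oracle = {
        p <- rep(NA_real_, nrow(mort))
        for (f in folds) p[f$val] <- mu[f$val]
        p
      })
    if (s == "fd") {
      mth <- as.integer(format(mort$date, "%m"))
      preds[s, !(mth %in% 6:8)] <- NA_real_
    }
  }
  raw <- t(apply(preds, 1L, rrmse_by_doy, obs = mort))
  smth <- t(apply(raw, 1L, function(r) {
    if (all(is.na(r))) r else loess_smooth(r, cfg$eval$loess_span)
  }))
  structure(list(strategies = strategies, rrmse_raw = raw,
                 rrmse_smooth = smth, predictions = preds,
                 fold_log = fold_log, dates = mort$date),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d strategies, %d days>\n",
              length(x$strategies), ncol(x$predictions)))
  m <- rowMeans(x$rrmse_raw, na.rm = TRUE)
  for (s in x$strategies)
    cat(sprintf("  %-7s mean rRMSE %.4f\n", s, m[s]))
  invisible(x)
}

#' @export
plot.cv_report <- function(x, smoothed = TRUE, ...) {
  m <- if (smoothed) x$rrmse_smooth else x$rrmse_raw
  graphics::matplot(1:365, t(m), type = "l", lty = 1,
                    xlab = "day of year", ylab = "rRMSE", ...)
  graphics::legend("topright", legend = x$strategies, lty = 1,
                   col = seq_len(nrow(m)), bty = "n")
  invisible(x)
}

## ---- per-strategy fold prediction engines ---------------------------------

## DLNM / AG (window > 1 aggregates the training response per contiguous
## training segment).  The design is rebuilt per fold from training
## temperature quantiles; trend basis knots come from the full date index
## (deterministic in the dates).
cv_predict_dlnm <- function(mort, temp, cfg, folds, window = 1L) {
  n <- nrow(mort)
  pred <- rep(NA_real_, n)
  tr_full <- trend_spline(mort$date, cfg$dlnm$trend_df_per_decade)
  se_full <- seasonal_harmonics(mort$date, cfg$dlnm$seasonal_pairs)
  for (f in folds) {
    trn <- which(f$train)
    x_trn <- temp$value[trn]
    var_knots <- unname(quantile(x_trn, cfg$dlnm$var_knot_probs, type = 7))
    var_boundary <- range(temp$value)  # covers validation temperatures
    cb <- build_cross_basis(temp, cfg, var_knots = var_knots,
                            var_boundary = var_boundary)
    X <- cbind(1, cb$Q, tr_full, se_full)
    y <- mort$value
    if (window > 1L) {
      y <- rep(NA_real_, n)
      for (seg in split(trn, cumsum(c(1L, diff(trn) != 1L)))) {
        segser <- daily_series(mort$date[seg], mort$value[seg], "count")
        y[seg] <- causal_kernel_smooth(segser, window)$value
      }
    }
    fit_rows <- intersect(trn, which(cb$complete))
    qp <- fit_quasipoisson(y[fit_rows], X[fit_rows, , drop = FALSE])
    val_rows <- intersect(which(f$val), which(cb$complete))
    pred[val_rows] <- exp(drop(X[val_rows, , drop = FALSE] %*% qp$coefficients))
  }
  pred
}

## EMDR: one full-series decomposition, Lasso refit per fold
cv_predict_emdr <- function(mort, temp, cfg, folds) {
  dec <- na_memd(temp, cfg)
  Z <- cbind(dec$imfs, dec$residual)
  n <- nrow(mort)
  pred <- rep(NA_real_, n)
  for (f in folds) {
    trn <- which(f$train)
    ctr <- colMeans(Z[trn, , drop = FALSE])
    scl <- apply(Z[trn, , drop = FALSE], 2L, sd)
    Zs <- scale(Z, center = ctr, scale = scl)
    cv <- cv_select_lambda(Zs[trn, , drop = FALSE], mort$value[trn],
                           folds = cfg$emdr$folds, seed = cfg$seed,
                           n_lambda = cfg$emdr$n_lambda)
    eta <- drop(predict(cv$cv_fit, newx = Zs, s = cv$lambda,
                        type = "link"))
    pred[f$val] <- exp(eta[f$val])
  }
  pred
}

## FY: year-curve model refitted per fold with a 30-day guard
cv_predict_fy <- function(mort, temp, cfg, folds) {
  mc <- to_year_curves(mort)
  tc <- to_year_curves(temp)
  n <- nrow(mort)
  pred <- rep(NA_real_, n)
  doy <- doy365(mort$date)
  yr <- as.integer(format(mort$date, "%Y"))
  for (f in folds) {
    vy <- f$year
    others <- setdiff(mc$years, vy)
    excl <- matrix(FALSE, length(mc$years), 365L)
    iy <- match(vy, mc$years)
    if (iy > 1L) excl[iy - 1L, (365L - 29L):365L] <- TRUE
    if (iy < length(mc$years)) excl[iy + 1L, 1:30] <- TRUE
    fit <- fit_fy(mc, tc, cfg, fit_years = others, exclude = excl)
    rows <- which(yr == vy)
    pred[rows] <- fit$mu[as.character(vy), doy[rows]]
  }
  pred
}

## FD: daily functional model refitted per fold with a 1-day guard
cv_predict_fd <- function(mort, hourly, cfg, folds) {
  n <- nrow(mort)
  pred <- rep(NA_real_, n)
  for (f in folds) {
    fit <- fit_fd(mort, hourly, cfg, fit_dates = mort$date[f$train])
    rows <- which(f$val)
    m <- match(mort$date[rows], fit$dates)
    pred[rows[!is.na(m)]] <- fit$mu[m[!is.na(m)]]
  }
  pred
}
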
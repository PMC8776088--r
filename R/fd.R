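## FD strategy: scalar-on-function regression of the daily death count on
## the previous day's hourly temperature curve.

#' Fit the daily functional model
#'
#' Models `log mu_t = alpha + trend(t) + dow(t) + (1/24) sum_h beta(h)
#' x_{t-1}(h)`, where `x_{t-1}` is the previous day's 24-hour temperature
#' curve and `beta(h)` a cubic penalized spline with 2 regularly placed
#' interior knots. A smooth P-spline over the day index captures the
#' inter-annual mortality trend, and a day-of-week factor enters
#' unpenalized. Fitting is by [boost()] with Poisson loss, step 0.1,
#' stopping iteration by day-level 10-fold cross-validation up to 100
#' steps. The hourly integral is discretized as the mean over the 24
#' points, so `beta(h)` is a log-rate change per degC sustained for a day.
#'
#' @param mort a count [daily_series()].
#' @param hourly an [hourly_series()] covering at least the mortality dates
#'   minus the first day.
#' @param cfg a [run_config()].
#' @param fit_dates optional subset of dates entering the loss (default
#'   all); the design is built for every predictable day.
#' @return An object of class `fd_fit` with the boosting fit, the hourly
#'   coefficient curve `$beta` (length 24), fitted expectations `$mu` with
#'   their `$dates`, and the basis.
#' @export
fit_fd <- function(mort, hourly, cfg = run_config(), fit_dates = NULL) {
  stopifnot(inherits(mort, "daily_series"), inherits(hourly, "hourly_series"))
  hm <- hourly_matrix(hourly)
  # predictable days: mortality days whose previous day has an hourly curve
  prev_idx <- match(mort$date - 1L, hm$dates)
  usable <- which(!is.na(prev_idx))
  if (length(usable) < 60L)
    stop("hourly series does not cover the mortality dates (minus one day)")
  dates <- mort$date[usable]
  y <- mort$value[usable]
  W <- hm$values[prev_idx[usable], , drop = FALSE]

  B_h <- fd_hour_basis(cfg$fd$knots)
  Xf <- (W %*% B_h) / 24
  D2 <- crossprod(diff(diag(ncol(B_h)), differences = 2L))

  n <- length(usable)
  day_idx <- as.numeric(dates - dates[1L])
  # the smooth time term captures the inter-annual trend only (knots every
  # ~6 months, 3 edf); seasonality is not modelled separately here
  n_time_knots <- max(3L, round(n / 182.5))
  wd <- factor(as.integer(format(dates, "%u")), levels = 1:7)
  Xdow <- stats::model.matrix(~wd)[, -1L, drop = FALSE]

  in_fit <- if (is.null(fit_dates)) rep(TRUE, n) else dates %in% fit_dates
  rows <- which(in_fit)

  time_basis <- fd_time_basis(day_idx, n_time_knots)
  Pt <- crossprod(diff(diag(ncol(time_basis)), differences = 2L))
  learners <- list(
    base_learner(Xf[rows, , drop = FALSE], D2, df = cfg$fd$df,
                 name = "hour_curve"),
    base_learner(time_basis[rows, , drop = FALSE], Pt, df = 3,
                 name = "time"),
    base_learner(Xdow[rows, , drop = FALSE], NULL, name = "dow"))
  cv <- cv_mstop(y[rows], learners, unit_id = rows,
                 n_folds = cfg$fd$folds, family = "poisson",
                 nu = cfg$fd$step, mstop_max = cfg$fd$mstop_max,
                 seed = cfg$seed)
  bf <- boost(y[rows], learners, family = "poisson", nu = cfg$fd$step,
              mstop = cv$mstop)

  beta <- drop(B_h %*% bf$coef$hour_curve)
  eta <- bf$f0 + drop(Xf %*% bf$coef$hour_curve) +
    drop(time_basis %*% bf$coef$time) + drop(Xdow %*% bf$coef$dow)
  structure(list(boost = bf, cv = cv, beta = beta, mu = exp(eta),
                 dates = dates, B_h = B_h, cfg = cfg,
                 lambdas = c(hour_curve = learners[[1L]]$lambda,
                             time = learners[[2L]]$lambda),
                 data = list(y = y, Xf = Xf, time_basis = time_basis,
                             Xdow = Xdow, rows = rows, day_idx = day_idx,
                             Pt = Pt, D2 = D2)),
            class = "fd_fit")
}

## cubic basis over clock hours 0..23 with equispaced interior knots
fd_hour_basis <- function(n_knots) {
  knots <- seq(0, 23, length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  bspline_design(0:23, knots, 3L, c(0, 23))
}

fd_time_basis <- function(day_idx, n_knots) {
  knots <- seq(min(day_idx), max(day_idx),
               length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  bspline_design(day_idx, knots, 3L, range(day_idx))
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<fd_fit: %d days, mstop %d (CV)>\n",
              length(x$dates), x$boost$mstop))
  cat(sprintf("  beta(hour) range: [%.4f, %.4f] per degC-day\n",
              min(x$beta), max(x$beta)))
  invisible(x)
}

#' @export
coef.fd_fit <- function(object, ...) object$beta

#' @export
predict.fd_fit <- function(object, ...) {
  data.frame(date = object$dates, mu = object$mu)
}

#' Hourly coefficient curve with bootstrap bands
#'
#' The effect of the previous day's temperature at each clock hour on the
#' daily death count, as fitted by [fit_fd()]. 95% bands come from a
#' nonparametric bootstrap over week blocks (consecutive 7-day groups
#' resampled with replacement), refitting at the selected stopping
#' iteration.
#'
#' @param fit an `fd_fit`.
#' @param boot number of bootstrap resamples (0 = no bands).
#' @param seed bootstrap seed; defaults to the fit's configuration seed.
#' @return A data frame with `hour`, `beta`, `rr` (per degC sustained for a
#'   day) and, with `boot > 0`, `lo95`, `hi95` on the RR scale.
#' @export
fd_hour_curve <- function(fit, boot = 100L, seed = NULL) {
  stopifnot(inherits(fit, "fd_fit"))
  out <- data.frame(hour = 0:23, beta = fit$beta, rr = exp(fit$beta / 24))
  if (boot > 0L) {
    if (is.null(seed)) seed <- fit$cfg$seed
    rows <- fit$data$rows
    blk <- (seq_along(rows) - 1L) %/% 7L + 1L
    curves <- matrix(NA_real_, boot, 24L)
    with_seed(seed, {
      for (b in seq_len(boot)) {
        take <- sample(unique(blk), length(unique(blk)), replace = TRUE)
        idx <- rows[unlist(lapply(take, function(g) which(blk == g)))]
        learners <- list(
          base_learner_fixed(fit$data$Xf[idx, , drop = FALSE], fit$data$D2,
                             lambda = fit$lambdas[["hour_curve"]],
                             name = "hour_curve"),
          base_learner_fixed(fit$data$time_basis[idx, , drop = FALSE],
                             fit$data$Pt, lambda = fit$lambdas[["time"]],
                             name = "time"),
          base_learner(fit$data$Xdow[idx, , drop = FALSE], NULL, name = "dow"))
        bf <- boost(fit$data$y[idx], learners, family = "poisson",
                    nu = fit$cfg$fd$step, mstop = fit$boost$mstop)
        curves[b, ] <- drop(fit$B_h %*% bf$coef$hour_curve)
      }
    })
    out$lo95 <- exp(apply(curves, 2L, quantile, 0.025, type = 7) / 24)
    out$hi95 <- exp(apply(curves, 2L, quantile, 0.975, type = 7) / 24)
  }
  out
}

#' @export
plot.fd_fit <- function(x, ...) {
  graphics::plot(0:23, x$beta, type = "l", xlab = "hour of previous day",
                 ylab = "beta(hour), log rate per degC-day", ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
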
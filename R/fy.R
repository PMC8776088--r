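## FY strategy: functional historical linear model on annual curves.  Each
## day-of-year of the mortality curve is regressed on the trailing 31-day
## window of the temperature curve through a smooth coefficient surface
## beta(lag, day-of-year), fitted by component-wise gradient boosting with
## Poisson loss.

#' Fit the yearly functional historical model
#'
#' Models `log mu_y(t) = alpha + trend(y) + sum_s beta(s, t) x_y(t - s)`
#' over day-of-year `t` and lag `s = 0..lag`, where the exposure history
#' crosses into the previous year's tail so winter days keep their full lag
#' window; the first year's initial `lag` days (which have no history) are
#' excluded from the loss. The coefficient surface is a tensor-product
#' cubic P-spline with 4 effective degrees of freedom per margin; the
#' inter-annual trend is an unpenalized 3-df natural spline over the year
#' index. Fitting is by [boost()] with Poisson loss, step 0.1 and the
#' stopping iteration chosen by year-wise 10-fold cross-validation up to
#' 100 steps.
#'
#' @param mort_curves mortality [to_year_curves()] object.
#' @param temp_curves temperature [to_year_curves()] on the same years.
#' @param cfg a [run_config()].
#' @param fit_years years whose observations enter the loss (default all);
#'   the design is always built for every year so held-out years can be
#'   predicted.
#' @param exclude optional logical matrix (years x 365) of additional
#'   observations to drop from the loss (e.g. guard margins).
#' @return An object of class `fy_fit` with the boosting fit, the
#'   discretized coefficient surface `$beta` (`(lag+1) x 365`), fitted
#'   expectations `$mu` (years x 365 matrix, `NA` where no lag history),
#'   and the bases needed to rebuild curves.
#' @export
fit_fy <- function(mort_curves, temp_curves, cfg = run_config(),
                   fit_years = NULL, exclude = NULL) {
  stopifnot(inherits(mort_curves, "year_curves"),
            inherits(temp_curves, "year_curves"))
  if (!identical(mort_curves$years, temp_curves$years))
    stop("mortality and temperature curves must cover the same years")
  Y <- length(mort_curves$years)
  if (Y < 3L) stop("at least 3 complete years are required")
  L <- cfg$fy$lag
  n_obs <- Y * 365L
  long_y <- as.vector(t(mort_curves$values))
  long_x <- as.vector(t(temp_curves$values))
  obs_year <- rep(seq_len(Y), each = 365L)
  obs_doy <- rep(1:365, Y)

  # trailing exposure window, crossing the year boundary via the flattened
  # series; the first L observations have no full history
  has_hist <- seq_len(n_obs) > L
  Xh <- matrix(NA_real_, n_obs, L + 1L)
  for (s in 0:L)
    Xh[(L + 1L):n_obs, s + 1L] <- long_x[(L + 1L):n_obs - s]

  # tensor-product functional design: rows Z[o, (j,k)] = H[o,j] * C[o,k]
  B_lag <- fy_lag_basis(L, cfg$fy$n_knots)
  C_doy <- fy_doy_basis(cfg$fy$n_knots)
  H <- Xh %*% B_lag
  Cm <- C_doy[obs_doy, , drop = FALSE]
  ps <- ncol(B_lag); pt <- ncol(C_doy)
  Z <- matrix(NA_real_, n_obs, ps * pt)
  for (j in seq_len(ps))
    Z[, (j - 1L) * pt + seq_len(pt)] <- H[, j] * Cm
  D2 <- function(p) crossprod(diff(diag(p), differences = 2L))
  P_tensor <- kronecker(D2(ps), diag(pt)) + kronecker(diag(ps), D2(pt))

  Tr <- fy_trend_basis(seq_len(Y), cfg$fy$trend_df)[obs_year, , drop = FALSE]

  if (is.null(fit_years)) fit_years <- mort_curves$years
  in_fit <- has_hist & (mort_curves$years[obs_year] %in% fit_years)
  if (!is.null(exclude)) in_fit <- in_fit & !as.vector(t(exclude))
  rows <- which(in_fit)
  if (length(rows) < 365L) stop("too few observations left to fit")

  learners <- list(
    base_learner(Z[rows, , drop = FALSE], P_tensor,
                 df = cfg$fy$df_margin^2, name = "surface"),
    base_learner(Tr[rows, , drop = FALSE], NULL, name = "trend"))
  cv <- cv_mstop(long_y[rows], learners, unit_id = obs_year[rows],
                 n_folds = cfg$fy$folds, family = "poisson",
                 nu = cfg$fy$step, mstop_max = cfg$fy$mstop_max,
                 seed = cfg$seed)
  bf <- boost(long_y[rows], learners, family = "poisson",
              nu = cfg$fy$step, mstop = cv$mstop)

  theta <- bf$coef$surface
  beta <- B_lag %*% t(matrix(theta, pt, ps)) %*% t(C_doy)
  eta <- rep(NA_real_, n_obs)
  eta[has_hist] <- bf$f0 +
    drop(Z[has_hist, , drop = FALSE] %*% theta) +
    drop(Tr[has_hist, , drop = FALSE] %*% bf$coef$trend)
  mu <- matrix(exp(eta), Y, 365L, byrow = TRUE,
               dimnames = list(mort_curves$years, NULL))

  structure(list(boost = bf, cv = cv, beta = beta, mu = mu,
                 years = mort_curves$years, fit_years = fit_years,
                 lag = L, B_lag = B_lag, C_doy = C_doy, cfg = cfg,
                 data = list(mort = mort_curves, temp = temp_curves,
                             rows = rows)),
            class = "fy_fit")
}

## cubic B-spline bases for the lag and day-of-year margins
fy_lag_basis <- function(L, n_knots) {
  knots <- seq(0, L, length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  bspline_design(0:L, knots, 3L, c(0, L))
}

fy_doy_basis <- function(n_knots) {
  knots <- seq(1, 365, length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  bspline_design(1:365, knots, 3L, c(1, 365))
}

fy_trend_basis <- function(year_idx, df) {
  if (df >= length(unique(year_idx)))
    stop("trend df must be below the number of years")
  unclass(splines::ns(year_idx, df = df))[, , drop = FALSE]
}

#' @export
print.fy_fit <- function(x, ...) {
  cat(sprintf("<fy_fit: %d years, lag 0..%d, mstop %d (CV)>\n",
              length(x$years), x$lag, x$boost$mstop))
  cum <- colSums(x$beta)
  cat(sprintf("  cumulative log-RR range over the year: [%.4f, %.4f]\n",
              min(cum), max(cum)))
  invisible(x)
}

#' @export
coef.fy_fit <- function(object, ...) object$beta

#' @export
predict.fy_fit <- function(object, ...) object$mu

#' Cumulative relative-risk curve over the year
#'
#' Sums the fitted coefficient surface along the lag dimension at each
#' day-of-year: the relative risk of a sustained +1 degC temperature
#' deviation over the whole lag window, as a function of when in the year
#' it occurs. Optional 95% bands come from a nonparametric bootstrap over
#' years (refitting at the selected stopping iteration).
#'
#' @param fit an `fy_fit`.
#' @param boot number of bootstrap resamples (0 = no bands).
#' @param seed seed for the bootstrap; defaults to the fit's configuration
#'   seed.
#' @return A data frame with `doy`, `rr` and (with `boot > 0`) `lo95`,
#'   `hi95`.
#' @export
fy_cumulative_rr <- function(fit, boot = 100L, seed = NULL) {
  stopifnot(inherits(fit, "fy_fit"))
  rr <- exp(colSums(fit$beta))
  out <- data.frame(doy = 1:365, rr = rr)
  if (boot > 0L) {
    if (is.null(seed)) seed <- fit$cfg$seed
    cum <- fy_boot_cumulative(fit, boot, seed)
    out$lo95 <- exp(apply(cum, 2L, quantile, 0.025, type = 7))
    out$hi95 <- exp(apply(cum, 2L, quantile, 0.975, type = 7))
  }
  out
}

## bootstrap over years: resample fitting years with replacement, refit the
## boosting at the selected mstop, return cumulative log-RR curves (B x 365)
fy_boot_cumulative <- function(fit, boot, seed) {
  rows <- fit$data$rows
  obs_year <- rep(seq_along(fit$years), each = 365L)[rows]
  long_y <- as.vector(t(fit$data$mort$values))[rows]
  ps <- ncol(fit$B_lag); pt <- ncol(fit$C_doy)
  refit <- refit_designs_fy(fit)
  cum <- matrix(NA_real_, boot, 365L)
  yrs <- seq_along(fit$years)[fit$years %in% fit$fit_years]
  with_seed(seed, {
    for (b in seq_len(boot)) {
      take <- sample(yrs, length(yrs), replace = TRUE)
      idx <- unlist(lapply(take, function(yy) which(obs_year == yy)))
      learners <- list(
        base_learner_fixed(refit$Z[idx, , drop = FALSE], refit$P,
                           fit$boost$coef, lambda = refit$lambda_surface,
                           name = "surface"),
        base_learner(refit$Tr[idx, , drop = FALSE], NULL, name = "trend"))
      bf <- boost(long_y[idx], learners, family = "poisson",
                  nu = fit$cfg$fy$step, mstop = fit$boost$mstop)
      theta <- bf$coef$surface
      cum[b, ] <- colSums(fit$B_lag %*% t(matrix(theta, pt, ps)) %*% t(fit$C_doy))
    }
  })
  cum
}

## designs restricted to the original fitting rows (cached on first use)
refit_designs_fy <- function(fit) {
  cfg <- fit$cfg
  L <- fit$lag
  Y <- length(fit$years)
  long_x <- as.vector(t(fit$data$temp$values))
  n_obs <- Y * 365L
  Xh <- matrix(NA_real_, n_obs, L + 1L)
  for (s in 0:L)
    Xh[(L + 1L):n_obs, s + 1L] <- long_x[(L + 1L):n_obs - s]
  H <- Xh %*% fit$B_lag
  obs_doy <- rep(1:365, Y)
  Cm <- fit$C_doy[obs_doy, , drop = FALSE]
  ps <- ncol(fit$B_lag); pt <- ncol(fit$C_doy)
  Z <- matrix(NA_real_, n_obs, ps * pt)
  for (j in seq_len(ps))
    Z[, (j - 1L) * pt + seq_len(pt)] <- H[, j] * Cm
  D2 <- function(p) crossprod(diff(diag(p), differences = 2L))
  P <- kronecker(D2(ps), diag(pt)) + kronecker(diag(ps), D2(pt))
  Tr <- fy_trend_basis(seq_len(Y), cfg$fy$trend_df)[rep(seq_len(Y), each = 365L), , drop = FALSE]
  rows <- fit$data$rows
  # lambda from the original calibration so bootstrap refits are comparable
  lam <- {
    XtX <- crossprod(Z[rows, , drop = FALSE])
    R <- chol(XtX + diag(1e-8 * mean(diag(XtX)), ncol(XtX)))
    A <- backsolve(R, t(backsolve(R, t(P), transpose = TRUE)), transpose = TRUE)
    e <- pmax(eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values, 0)
    tf <- function(loglam) sum(1 / (1 + 10^loglam * e)) - cfg$fy$df_margin^2
    10^uniroot(tf, c(-12, 12), tol = 1e-10)$root
  }
  list(Z = Z[rows, , drop = FALSE], Tr = Tr[rows, , drop = FALSE], P = P,
       lambda_surface = lam)
}

## learner with a pre-fixed ridge amount (no df re-calibration)
base_learner_fixed <- function(X, penalty, ..., lambda, name) {
  X <- as.matrix(X)
  XtX <- crossprod(X)
  K <- XtX + lambda * penalty + diag(1e-8 * mean(diag(XtX)), ncol(X))
  structure(list(X = X, K_chol = chol(K), lambda = lambda, df = NA_real_,
                 penalty = penalty, name = name),
            class = "base_learner")
}

#' @export
plot.fy_fit <- function(x, ...) {
  rr <- fy_cumulative_rr(x, boot = 0L)
  graphics::plot(rr$doy, rr$rr, type = "l", xlab = "day of year",
                 ylab = "cumulative RR (+1 degC sustained)", ...)
  graphics::abline(h = 1, col = "grey")
  invisible(x)
}
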
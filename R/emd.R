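## Empirical mode decomposition: univariate sifting, multivariate (MEMD)
## decomposition with projection envelopes, and the noise-assisted variant
## used to decompose the temperature exposure.

## Low-discrepancy direction vectors on the unit sphere in `dim` dimensions:
## Halton points (first `dim` prime bases) mapped through the normal quantile
## function and normalised, giving a deterministic quasi-uniform cover.
memd_directions <- function(n_dir, dim) {
  if (dim == 1L) return(matrix(1, 1L, 1L))
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (dim > length(primes)) stop("too many channels for direction generation")
  radical_inverse <- function(i, base) {
    f <- 1 / base; r <- 0
    while (i > 0) {
      r <- r + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    r
  }
  u <- sapply(primes[seq_len(dim)], function(b)
    vapply(seq_len(n_dir), radical_inverse, numeric(1L), base = b))
  z <- qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  z / sqrt(rowSums(z^2))
}

## One sifting pass shared by sift() and memd(): refine `h` (n x c matrix)
## until the Rilling criterion holds or max_sift iterations are spent.
## Returns NULL when the input has too few extrema to be sifted.
sift_once <- function(h, dirs, max_sift = 100L,
                      tol = c(0.05, 0.5, 0.95)) {
  for (it in seq_len(max_sift)) {
    env <- memd_mean_env(h, dirs)
    if (env$min_extrema < 2L || env$n_valid == 0L) {
      if (it == 1L) return(NULL)
      break
    }
    m <- env$mean
    # evaluate the criterion only where the local amplitude is defined;
    # envelope overshoot can pinch the amplitude to ~0 at isolated points
    ok <- env$amp > 1e-8 * max(env$amp, 0)
    sigma <- ifelse(ok, sqrt(rowSums(m^2)) / pmax(env$amp, 1e-300), 0)
    if (mean(sigma < tol[1L]) >= tol[3L] && max(sigma) < tol[2L]) break
    h <- h - m
  }
  h
}

## Channel-wise cleanup pass after a multivariate decomposition: sift each
## kept IMF univariately until the defining property holds (extrema and
## zero-crossing counts within 1 of each other), passing the removed part
## down to the next mode so the reconstruction identity is untouched.
refine_imf_cascade <- function(imfs, residual, max_iter = 300L) {
  dirs1 <- matrix(1, 1L, 1L)
  counts <- function(v) {
    n <- length(v)
    s <- sign(diff(v)); s <- s[s != 0]
    c(sum(abs(diff(s)) > 0), sum(v[-1L] * v[-n] < 0))
  }
  K <- ncol(imfs)
  for (k in seq_len(K)) {
    h <- imfs[, k]
    for (it in seq_len(max_iter)) {
      st <- counts(h)
      if (abs(st[1L] - st[2L]) <= 1L) break
      env <- memd_mean_env(matrix(h, ncol = 1L), dirs1)
      if (env$min_extrema < 2L || env$n_valid == 0L) break
      h <- h - env$mean[, 1L]
    }
    leftover <- imfs[, k] - h
    imfs[, k] <- h
    if (k < K) imfs[, k + 1L] <- imfs[, k + 1L] + leftover
    else residual <- residual + leftover
  }
  list(imfs = imfs, residual = residual)
}

#' Extract one intrinsic mode function by sifting
#'
#' Iteratively subtracts the mean of cubic-spline upper/lower envelopes
#' (mirror-extended at the boundaries) until the envelope-mean amplitude
#' ratio is below 0.05 on at least 95% of points and below 0.5 everywhere,
#' or 100 iterations are reached.
#'
#' @param signal numeric vector with at least 2 maxima and 2 minima.
#' @param max_sift maximum number of sifting iterations.
#' @return A list with components `imf` and `remainder`; their sum equals
#'   `signal` exactly.
#' @export
sift <- function(signal, max_sift = 100L) {
  signal <- as.numeric(signal)
  x <- matrix(signal, ncol = 1L)
  h <- sift_once(x, memd_directions(1L, 1L), max_sift)
  if (is.null(h))
    stop("signal has too few extrema to sift (monotone or residual-like)")
  list(imf = h[, 1L], remainder = signal - h[, 1L])
}

#' Multivariate empirical mode decomposition
#'
#' Decomposes an `n x c` multichannel signal into a shared set of intrinsic
#' mode functions using envelopes interpolated at the extrema of projections
#' onto low-discrepancy direction vectors. All channels yield the same
#' number of IMFs.
#'
#' @param X numeric matrix, one column per channel.
#' @param n_directions number of projection directions on the unit sphere.
#' @param max_imf,max_sift decomposition / sifting iteration caps.
#' @return A list with `imfs` (list of `n x c` matrices, highest frequency
#'   first) and `residual` (`n x c`), satisfying
#'   `Reduce("+", imfs) + residual == X` exactly.
#' @export
memd <- function(X, n_directions = 64L, max_imf = 20L, max_sift = 100L) {
  X <- as.matrix(X)
  dirs <- memd_directions(n_directions, ncol(X))
  residual <- X
  imfs <- list()
  while (length(imfs) < max_imf) {
    h <- sift_once(residual, dirs, max_sift)
    if (is.null(h)) break
    imfs[[length(imfs) + 1L]] <- h
    residual <- residual - h
  }
  list(imfs = imfs, residual = residual)
}

#' Mean period of an oscillating component
#'
#' Defined as twice the series length divided by the number of sign changes,
#' i.e. the average duration of a full oscillation in days for daily data.
#'
#' @param imf numeric vector with at least 2 zero crossings.
#' @return Mean period (same time unit as the sampling step).
#' @export
mean_period <- function(imf) {
  n <- length(imf)
  crossings <- sum(imf[-1L] * imf[-n] < 0)
  if (crossings < 2L)
    stop("fewer than 2 zero crossings: component is residual-like, period undefined")
  2 * n / crossings
}

#' Noise-assisted multivariate EMD of a temperature series
#'
#' Adds seeded Gaussian white-noise channels (standard deviation a fraction
#' of the signal's) to the temperature before the multivariate
#' decomposition, which prevents mode mixing by anchoring a full frequency
#' ladder in every sifting step. Noise-channel IMFs are discarded. The kept
#' signal IMFs then receive a univariate cleanup sift until each satisfies
#' the defining property (extrema and zero-crossing counts within one),
#' with the removed part cascaded into the next mode so the reconstruction
#' identity is preserved exactly; trend-like components without oscillation
#' are folded into the residual.
#'
#' @param signal a temperature [daily_series()] (length >= 512) or numeric
#'   vector.
#' @param cfg a [run_config()]; uses the `emdr` block and `seed`.
#' @param seed optional override of `cfg$seed`.
#' @return An object of class `imf_decomposition` with fields `imfs`
#'   (`n x K` matrix, highest frequency first), `residual`, `mean_periods`
#'   (days, increasing), `n_noise_channels`, `seed` and `dates`.
#' @export
na_memd <- function(signal, cfg = run_config(), seed = NULL) {
  dates <- NULL
  if (inherits(signal, "daily_series")) {
    dates <- signal$date
    x <- signal$value
  } else x <- as.numeric(signal)
  if (length(x) < 512L) stop("signal too short for decomposition (need >= 512)")
  if (sd(x) == 0) stop("degenerate (constant) input")
  ec <- cfg$emdr
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  noise <- with_seed(seed, {
    if (ec$n_noise > 0L)
      matrix(rnorm(length(x) * ec$n_noise, 0,
                   ec$noise_sd_fraction * sd(x)),
             ncol = ec$n_noise)
    else NULL
  })
  X <- cbind(x, noise)
  dec <- memd(X, n_directions = ec$n_directions, max_imf = ec$max_imf,
              max_sift = ec$max_sift)
  K <- length(dec$imfs)
  if (K == 0L) stop("no intrinsic mode function extracted")
  imfs <- vapply(dec$imfs, function(m) m[, 1L], numeric(length(x)))
  residual <- dec$residual[, 1L]
  ref <- refine_imf_cascade(imfs, residual)
  imfs <- ref$imfs
  residual <- ref$residual
  # fold non-oscillating tail components into the residual trend
  periods <- rep(NA_real_, ncol(imfs))
  for (k in seq_len(ncol(imfs))) {
    sc <- sum(imfs[-1L, k] * imfs[-nrow(imfs), k] < 0)
    if (sc >= 2L) periods[k] <- 2 * nrow(imfs) / sc
  }
  keep <- !is.na(periods)
  if (!all(keep)) {
    residual <- residual + rowSums(imfs[, !keep, drop = FALSE])
    imfs <- imfs[, keep, drop = FALSE]
    periods <- periods[keep]
  }
  structure(list(imfs = imfs, residual = residual,
                 mean_periods = periods,
                 n_noise_channels = ec$n_noise, seed = seed,
                 dates = dates),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition: %d IMFs + residual trend, n = %d>\n",
              ncol(x$imfs), nrow(x$imfs)))
  cat("  mean periods (days):",
      paste(sprintf("%.1f", x$mean_periods), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.imf_decomposition <- function(x, ...) {
  K <- ncol(x$imfs)
  op <- graphics::par(mfrow = c(K + 1L, 1L), mar = c(1, 4, 0.5, 1))
  on.exit(graphics::par(op))
  idx <- if (is.null(x$dates)) seq_len(nrow(x$imfs)) else x$dates
  for (k in seq_len(K))
    plot(idx, x$imfs[, k], type = "l", ylab = sprintf("IMF %d", k),
         xlab = "", xaxt = if (k < K) "n" else "s", ...)
  plot(idx, x$residual, type = "l", ylab = "residual", xlab = "", ...)
  invisible(x)
}
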
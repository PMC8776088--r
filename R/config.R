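#' Analysis configuration
#'
#' Collects every tuning constant used by the strategies in one validated
#' list, so a whole analysis is reproducible from the configuration plus a
#' seed. Defaults follow the settings used throughout the package
#' documentation: a 7-day causal aggregation window, a 21-day DLNM lag with
#' temperature knots at the 10th/75th/90th percentiles, 4 seasonal harmonic
#' pairs and 1 trend df per decade, two 20%-sd noise channels and 64
#' projection directions for the multivariate EMD, 10 cross-validation folds,
#' a 30-day functional lag with 4 df per margin for the yearly functional
#' model, 2 interior knots for the daily functional model, boosting step 0.1
#' with at most 100 iterations, and a 0.15-span circular LOESS for the
#' evaluation curves.
#'
#' @param ag list: `window` (days), `p_max` (max AR order).
#' @param dlnm list: `var_knot_probs`, `var_degree`, `max_lag`, `n_lag_knots`,
#'   `trend_df_per_decade`, `seasonal_pairs`.
#' @param emdr list: `n_noise`, `noise_sd_fraction`, `n_directions`, `folds`,
#'   `n_lambda`, `max_sift`, `max_imf`.
#' @param fy list: `lag`, `df_margin`, `trend_df`, `step`, `mstop_max`,
#'   `folds`, `n_knots`.
#' @param fd list: `knots`, `df`, `step`, `mstop_max`, `folds`.
#' @param eval list: `loess_span`; the guard gap is strategy-specific, see
#'   [hv_folds()].
#' @param seed integer seed used by every stochastic component.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(ag = list(), dlnm = list(), emdr = list(),
                       fy = list(), fd = list(), eval = list(),
                       seed = 1L) {
  merge <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    ag = merge(list(window = 7L, p_max = 5L), ag),
    dlnm = merge(list(var_knot_probs = c(0.10, 0.75, 0.90), var_degree = 2L,
                      max_lag = 21L, n_lag_knots = 3L,
                      trend_df_per_decade = 1, seasonal_pairs = 4L), dlnm),
    emdr = merge(list(n_noise = 2L, noise_sd_fraction = 0.2,
                      n_directions = 64L, folds = 10L, n_lambda = 100L,
                      max_sift = 100L, max_imf = 20L), emdr),
    fy = merge(list(lag = 30L, df_margin = 4, trend_df = 3L, step = 0.1,
                    mstop_max = 100L, folds = 10L, n_knots = 8L), fy),
    fd = merge(list(knots = 2L, df = 4, step = 0.1, mstop_max = 100L,
                    folds = 10L), fd),
    eval = merge(list(loess_span = 0.15), eval),
    seed = as.integer(seed)
  )
  with(cfg$dlnm, {
    if (any(diff(var_knot_probs) <= 0) || any(var_knot_probs <= 0) ||
        any(var_knot_probs >= 1))
      stop("var_knot_probs must be strictly increasing in (0,1)")
  })
  stopifnot(cfg$ag$window >= 1L, cfg$ag$p_max >= 0L,
            cfg$dlnm$max_lag >= 0L, cfg$dlnm$seasonal_pairs >= 1L,
            cfg$emdr$n_noise >= 0L, cfg$emdr$noise_sd_fraction >= 0,
            cfg$emdr$n_directions >= 1L, cfg$emdr$folds >= 2L,
            cfg$fy$lag >= 1L, cfg$fy$step > 0, cfg$fy$step <= 1,
            cfg$fd$step > 0, cfg$fd$step <= 1,
            cfg$eval$loess_span > 0, cfg$eval$loess_span <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in setdiff(names(x), "seed")) {
    vals <- vapply(x[[nm]], function(v) paste(format(v), collapse = "/"),
                   character(1L))
    cat(sprintf("  %-5s %s\n", nm,
                paste(names(vals), vals, sep = "=", collapse = ", ")))
  }
  cat("  seed ", x$seed, "\n", sep = "")
  invisible(x)
}
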
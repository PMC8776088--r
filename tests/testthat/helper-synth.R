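# Shared fixtures: small, fast ground-truth configurations used across the
# unit tests.  Everything is generated in code; no stored data.

# truth with no exposure effect and no short-term confounding;
# any field can still be overridden
null_truth <- function(...) {
  args <- list(f = function(t) rep(0, length(t)),
               seasonal_amp = 0, trend_slope = 0,
               dow_effects = rep(1, 7))
  user <- list(...)
  do.call(synth_truth, c(user, args[setdiff(names(args), names(user))]))
}

# noise-free temperature process (pure deterministic components)
quiet_temp_truth <- function(...) {
  synth_truth(temp_ar1 = 0, temp_noise_sd = 0, temp_osc = list(), ...)
}

# a short aligned mortality/temperature pair for fitting tests
small_sim <- function(n_days = 1100, seed = 42, truth = synth_truth(),
                      start = as.Date("2000-01-01")) {
  temp <- simulate_temperature(n_days, truth, seed = seed, start = start)
  mort <- simulate_mortality(temp, truth, seed = seed + 1L, return_mu = TRUE)
  list(temp = temp, mort = mort, truth = truth)
}
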
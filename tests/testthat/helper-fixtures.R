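# Shared fixtures: small grids and scenarios sized for fast test runs.

fast_grid <- function(duration = 504)
  spatial_grid(n_cells = 50, time_step = 0.5, duration = duration)

# one-compound scenario on flowpath b with known truth
one_compound_spec <- function(k = 0.0189, R = 1, noise = 0.05, seed = 42,
                              flowpath = "b", k_sw = 0.011, loq = 0.01) {
  truth <- stats::setNames(list(list(k = k, R = R)), flowpath)
  scenario_spec(
    compounds = list(x = list(k_sw = k_sw, loq = loq, truth = truth)),
    noise_rel_sd = noise, seed = seed)
}

# settings small enough for unit tests (not for production inference)
fast_settings <- function(n_generations = 600, seed = 1, ...)
  dream_settings(n_generations = n_generations, seed = seed,
                 grid = spatial_grid(n_cells = 40, time_step = 1), ...)
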
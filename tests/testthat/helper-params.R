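# small parameter sets used across tests

tiny_params <- function(n = 6L, ...) {
  defaults <- list(n_agents = n, n_small = n %/% 2L,
                   sigma_small = 0.1, sigma_large = 0.15,
                   n_iterations = 100L, measure_every = 10L, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_params, args)
}

# noiseless params: useful for fixed-point and hand-computed checks
quiet_params <- function(n = 3L, ...) {
  tiny_params(n = n, noise_half_width = 0, ...)
}
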
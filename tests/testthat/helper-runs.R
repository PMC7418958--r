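# Shared simulation runs for the acceptance checks, computed once per test
# session and cached. Problem sizes: equal groups of 20, delta = 0.2, k = 3,
# sigma_S = 0.1, sigma_L = 1.5 sigma_S; the occupancy/ceiling runs use
# 100,000 iterations with snapshots every 1,000; the stationary directional
# comparisons use the full 500,000-iteration horizon with the standard
# 10,000-iteration cadence; 10 replicas each, trailing-50% windows.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

occupancy_runs <- function() {
  cached("occupancy", {
    p <- model_params(n_agents = 40L, n_small = 20L,
                      sigma_small = 0.1, sigma_large = 0.15,
                      noise_half_width = 0.2, gossip_count = 3L,
                      n_iterations = 100000L, measure_every = 1000L,
                      seed = 1L)
    run_replicas(p, 10L)
  })
}

stationary_runs <- function() {
  cached("stationary", {
    p <- model_params(n_agents = 40L, n_small = 20L,
                      sigma_small = 0.1, sigma_large = 0.15,
                      noise_half_width = 0.2, gossip_count = 3L,
                      n_iterations = 500000L, measure_every = 10000L,
                      seed = 1L)
    run_replicas(p, 10L)
  })
}

baseline_runs <- function() {
  cached("baseline", {
    p <- model_params(n_agents = 40L, n_small = 40L, n_large = 0L,
                      sigma_small = 0.1, sigma_large = 1,
                      noise_half_width = 0.2, gossip_count = 3L,
                      n_iterations = 500000L, measure_every = 10000L,
                      seed = 1L)
    run_replicas(p, 10L)
  })
}
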
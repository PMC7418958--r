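#' Run one replica of the influence-Leviathan model
#'
#' Initialises all esteems to zero, seeds the random stream from
#' `params$seed`, runs `params$n_iterations` iterations and records the full
#' esteem matrix at iteration 0, at every `params$measure_every` iterations,
#' and at the final iteration.
#'
#' Two engines are available: `"compiled"` (the C++ production engine) and
#' `"reference"` (a naive R loop). Both consume the random stream
#' identically, so with the same parameters they produce bit-identical
#' series; the reference engine exists for readability and as an independent
#' check of the compiled one, and is orders of magnitude slower.
#'
#' @param params a [model_params()] object.
#' @param groups a [group_assignment()]; derived from `params` when `NULL`.
#' @param engine `"compiled"` or `"reference"`.
#' @param replica_id integer tag stored in the series.
#' @param stationary_window fraction in (0, 1] of trailing snapshots treated
#'   as the stationary regime by time-averaged indicators.
#' @return An object of class `snapshot_series`: list with `params`,
#'   `groups`, `times` (iteration counts of the snapshots), `snapshots`
#'   (list of esteem matrices), `replica_id` and `stationary_window`.
#' @examples
#' p <- model_params(n_agents = 10, n_small = 5, n_iterations = 200,
#'                   measure_every = 50, seed = 7)
#' s <- run_simulation(p)
#' s$times
#' @export
run_simulation <- function(params, groups = NULL,
                           engine = c("compiled", "reference"),
                           replica_id = 0L, stationary_window = 0.5) {
  engine <- match.arg(engine)
  validate_model_params(params)
  if (is.null(groups)) groups <- group_assignment(params)
  stopifnot(inherits(groups, "group_assignment"),
            length(groups$labels) == params$n_agents)
  if (stationary_window <= 0 || stationary_window > 1) {
    stop("stationary_window must lie in (0, 1]", call. = FALSE)
  }

  set.seed(params$seed)
  init <- matrix(0, params$n_agents, params$n_agents)

  if (engine == "compiled") {
    res <- cpp_simulate(init,
                        as.integer(groups$labels == "L"),
                        groups$sigma,
                        params$noise_half_width,
                        params$gossip_count,
                        params$same_group_prob,
                        params$esteem_bounds,
                        params$n_iterations,
                        params$measure_every)
    times <- res$times
    snapshots <- res$snapshots
  } else {
    state <- esteem_state(params$n_agents)
    times <- 0L
    snapshots <- list(state$a)
    record_at <- seq.int(params$measure_every, params$n_iterations,
                         by = params$measure_every)
    if (params$n_iterations > 0L &&
        (length(record_at) == 0L ||
         record_at[length(record_at)] != params$n_iterations)) {
      record_at <- c(record_at, params$n_iterations)
    }
    for (t in seq_len(params$n_iterations)) {
      state <- run_iteration(state, params, groups)
      if (t %in% record_at) {
        times <- c(times, t)
        snapshots <- c(snapshots, list(state$a))
      }
    }
  }

  series <- list(params = params, groups = groups,
                 times = as.integer(times), snapshots = snapshots,
                 replica_id = as.integer(replica_id),
                 stationary_window = stationary_window)
  class(series) <- "snapshot_series"
  series
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat(sprintf(
    "Snapshot series: replica %d, %d agents, %d snapshots (t = %d..%d)\n",
    x$replica_id, x$params$n_agents, length(x$times),
    x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Indices of the stationary-window snapshots of a series
#'
#' The trailing `stationary_window` fraction of snapshots (at least one),
#' used by all time-averaged indicators.
#'
#' @param series a `snapshot_series`.
#' @return Integer indices into `series$times` / `series$snapshots`.
#' @export
stationary_indices <- function(series) {
  n <- length(series$times)
  keep <- max(1L, as.integer(ceiling(series$stationary_window * n)))
  seq.int(n - keep + 1L, n)
}

#' Run several independently seeded replicas
#'
#' Replica r uses seed `params$seed + r`, so replicas are reproducible and
#' independent of execution order.
#'
#' @param params a [model_params()] object; its `seed` is the base seed.
#' @param n_replicas number of replicas.
#' @param ... passed to [run_simulation()].
#' @return A list of `snapshot_series`, replica ids 1..n_replicas.
#' @export
run_replicas <- function(params, n_replicas, ...) {
  stopifnot(n_replicas >= 1L)
  lapply(seq_len(n_replicas), function(r) {
    pr <- params
    pr$seed <- params$seed + as.integer(r)
    run_simulation(pr, replica_id = r, ...)
  })
}
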
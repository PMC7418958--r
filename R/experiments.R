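#' Open-mindedness of the L-group from the S-group's value
#'
#' Two relationship rules tie the groups' open-mindedness values together:
#' `f1`: sigma_L = 1.5 sigma_S, and `f2`: sigma_L = sigma_S + 0.1. The two
#' rules agree exactly at sigma_S = 0.2.
#'
#' @param sigma_small the S-group's open-mindedness (> 0).
#' @param rule `"f1"` or `"f2"`.
#' @return sigma_large.
#' @export
sigma_relation <- function(sigma_small, rule = c("f1", "f2")) {
  rule <- match.arg(rule)
  stopifnot(all(sigma_small > 0))
  switch(rule, f1 = 1.5 * sigma_small, f2 = sigma_small + 0.1)
}

#' Default simulation horizon for a given S-group open-mindedness
#'
#' Smaller sigma_S slows convergence, so the horizon grows as sigma_S
#' shrinks: `max(500000, round(50000 / sigma_small))` iterations.
#'
#' @inheritParams sigma_relation
#' @return Integer number of iterations.
#' @export
default_horizon <- function(sigma_small) {
  as.integer(pmax(500000, round(50000 / sigma_small)))
}

#' Configuration of a parameter sweep
#'
#' Bundles the grids and run-scale knobs for the scripted experiment designs.
#' The default grids are the study design this package targets: 14 sigma_S
#' values, group sizes 0..40 by 5, gossip counts 0..3, 50 replicas for the
#' sigma sweep and 30 for the size sweep. `scale_factor` multiplies horizon
#' and replica count for desk-scale runs (e.g. 0.1 for a quick look);
#' qualitative orderings are stable under such down-scaling.
#'
#' @param sigma_small_grid positive reals to sweep for sigma_S.
#' @param sigma_relation `"f1"`, `"f2"` or `"both"`.
#' @param n_small_grid S-group sizes to sweep (size sweep).
#' @param gossip_grid gossip counts k to sweep (size sweep).
#' @param replicas replicas per cell (sigma sweep default 50).
#' @param size_replicas replicas per cell of the size sweep (default 30).
#' @param base_seed base seed; cell and replica seeds are derived from it.
#' @param n_agents total population size.
#' @param noise_half_width,gossip_count,same_group_prob,measure_every
#'   passed through to [model_params()].
#' @param n_iterations horizon; `NA` (default) uses
#'   [default_horizon()] per sigma_S.
#' @param stationary_window trailing fraction of snapshots used for
#'   time-averaged indicators.
#' @param scale_factor positive real multiplying horizon and replicas.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(sigma_small_grid = c(0.03, 0.05, 0.07, 0.1, 0.12,
                                              0.2, 0.25, 0.3, 0.35, 0.4,
                                              0.5, 1, 2, 3),
                         sigma_relation = c("f1", "f2", "both"),
                         n_small_grid = seq(0L, 40L, by = 5L),
                         gossip_grid = 0:3,
                         replicas = 50L,
                         size_replicas = 30L,
                         base_seed = 1L,
                         n_agents = 40L,
                         noise_half_width = 0.2,
                         gossip_count = 3L,
                         same_group_prob = 0.5,
                         n_iterations = NA_integer_,
                         measure_every = 10000L,
                         stationary_window = 0.5,
                         scale_factor = 1) {
  sigma_relation <- match.arg(sigma_relation)
  stopifnot(length(sigma_small_grid) >= 1L, all(sigma_small_grid > 0),
            length(n_small_grid) >= 1L, length(gossip_grid) >= 1L,
            replicas >= 1L, size_replicas >= 1L, scale_factor > 0)
  cfg <- list(sigma_small_grid = as.numeric(sigma_small_grid),
              sigma_relation = sigma_relation,
              n_small_grid = as.integer(n_small_grid),
              gossip_grid = as.integer(gossip_grid),
              replicas = as.integer(replicas),
              size_replicas = as.integer(size_replicas),
              base_seed = as.integer(base_seed),
              n_agents = as.integer(n_agents),
              noise_half_width = as.numeric(noise_half_width),
              gossip_count = as.integer(gossip_count),
              same_group_prob = as.numeric(same_group_prob),
              n_iterations = as.integer(n_iterations),
              measure_every = as.integer(measure_every),
              stationary_window = as.numeric(stationary_window),
              scale_factor = as.numeric(scale_factor))
  class(cfg) <- "sweep_config"
  cfg
}

#' @export
print.sweep_config <- function(x, ...) {
  cat("Sweep configuration\n")
  cat("  sigma_S grid:", paste(x$sigma_small_grid, collapse = ", "), "\n")
  cat("  relation:", x$sigma_relation,
      " | N_S grid:", paste(x$n_small_grid, collapse = ", "), "\n")
  cat("  k grid:", paste(x$gossip_grid, collapse = ", "),
      " | replicas:", x$replicas, "(sigma) /", x$size_replicas, "(size)\n")
  cat(sprintf("  N=%d, delta=%g, k=%d, scale_factor=%g, base seed %d\n",
              x$n_agents, x$noise_half_width, x$gossip_count,
              x$scale_factor, x$base_seed))
  invisible(x)
}

relations_of <- function(cfg) {
  if (cfg$sigma_relation == "both") c("f1", "f2") else cfg$sigma_relation
}

effective_horizon <- function(cfg, sigma_small) {
  h <- if (is.na(cfg$n_iterations)) default_horizon(sigma_small)
       else cfg$n_iterations
  max(as.integer(round(h * cfg$scale_factor)), cfg$measure_every)
}

effective_replicas <- function(cfg, n) {
  max(1L, as.integer(round(n * cfg$scale_factor)))
}

cell_params <- function(cfg, sigma_small, sigma_large, n_small, gossip_count,
                        seed) {
  model_params(n_agents = cfg$n_agents,
               n_small = n_small,
               n_large = cfg$n_agents - n_small,
               sigma_small = sigma_small,
               sigma_large = sigma_large,
               noise_half_width = cfg$noise_half_width,
               gossip_count = gossip_count,
               same_group_prob = cfg$same_group_prob,
               n_iterations = effective_horizon(cfg, sigma_small),
               measure_every = cfg$measure_every,
               seed = seed)
}

# Stationary time-averaged group summary of a list of replicas, one row per
# (replica, group).
replica_cell_summary <- function(runs) {
  gs <- group_summary(runs, stationary = TRUE)
  gs[, .(mean_reputation = mean(mean_reputation),
         mean_self_esteem = mean(mean_self_esteem),
         cv_self_esteem = mean(cv_self_esteem),
         cv_reputation = mean(cv_reputation),
         sd_reputation = mean(sd_reputation)),
     by = .(replica, group)]
}

#' Single-group baseline runs at a given open-mindedness
#'
#' Runs the model with every agent in one group at open-mindedness
#' `sigma_small` (the comparison population for the two-group design) and
#' returns stationary time-averaged group summaries per replica, labelled
#' `design = "baseline"`.
#'
#' @param sigma_small the shared open-mindedness.
#' @param config a [sweep_config()].
#' @return A `data.table` with one row per replica.
#' @export
baseline_experiment <- function(sigma_small, config = sweep_config()) {
  reps <- effective_replicas(config, config$replicas)
  params <- model_params(n_agents = config$n_agents,
                         n_small = config$n_agents, n_large = 0L,
                         sigma_small = sigma_small,
                         sigma_large = sigma_small + 1,  # unused: L empty
                         noise_half_width = config$noise_half_width,
                         gossip_count = config$gossip_count,
                         same_group_prob = config$same_group_prob,
                         n_iterations = effective_horizon(config, sigma_small),
                         measure_every = config$measure_every,
                         seed = config$base_seed)
  runs <- run_replicas(params, reps,
                       stationary_window = config$stationary_window)
  out <- replica_cell_summary(runs)
  out[, `:=`(design = "baseline", sigma_small = sigma_small,
             sigma_large = sigma_small, relation = "none",
             n_small = config$n_agents, k = config$gossip_count,
             seed = config$base_seed,
             n_iterations = params$n_iterations)]
  out[]
}

#' Two-group sigma sweep with equal group sizes
#'
#' For every sigma_S in the grid and every relation rule, runs the two-group
#' model (N_S = N_L = N/2) over the configured replicas and collects the
#' full indicator set: per-replica stationary group summaries, pooled rank
#' occupancy, advancement probabilities and the glass-ceiling rank.
#' Individual replica failures are caught, flagged in the summary table and
#' the sweep continues.
#'
#' @param config a [sweep_config()].
#' @param out_dir optional directory for per-cell CSV caching; completed
#'   cells (detected by file presence) are skipped unless `force = TRUE`.
#' @param force rerun cells whose outputs already exist.
#' @return A list of `data.table`s: `group_summary`, `occupancy`,
#'   `advancement`, `glass_ceiling`.
#' @export
two_group_sweep <- function(config = sweep_config(), out_dir = NULL,
                            force = FALSE) {
  n_small <- config$n_agents %/% 2L
  summaries <- list()
  occupancy <- list()
  advancement <- list()
  ceiling_rows <- list()
  cell_id <- 0L
  for (relation in relations_of(config)) {
    for (ss in config$sigma_small_grid) {
      cell_id <- cell_id + 1L
      sl <- sigma_relation(ss, relation)
      key <- sprintf("sigma%s_%s", format(ss), relation)
      cache <- if (!is.null(out_dir)) {
        file.path(out_dir, paste0("cell_", key, "_summary.csv"))
      }
      if (!is.null(cache) && file.exists(cache) && !force) next
      seed <- config$base_seed + 10000L * cell_id
      reps <- effective_replicas(config, config$replicas)
      params <- cell_params(config, ss, sl, n_small, config$gossip_count,
                            seed)
      runs <- tryCatch(
        run_replicas(params, reps,
                     stationary_window = config$stationary_window),
        error = function(e) e)
      meta <- data.table::data.table(design = "two_group",
                                     sigma_small = ss, sigma_large = sl,
                                     relation = relation, n_small = n_small,
                                     k = config$gossip_count, seed = seed,
                                     n_iterations = params$n_iterations)
      if (inherits(runs, "error")) {
        warning("cell ", key, " failed: ", conditionMessage(runs),
                call. = FALSE)
        summaries[[key]] <- cbind(meta, data.table::data.table(
          replica = NA_integer_, group = NA_character_, status = "failed"))
        next
      }
      cs <- replica_cell_summary(runs)
      cs[, status := "ok"]
      summaries[[key]] <- cbind(meta[rep(1L, nrow(cs))], cs)
      ranks <- rank_records(runs, stationary = TRUE)
      occ <- occupancy_probability(ranks)
      occupancy[[key]] <- cbind(meta[rep(1L, nrow(occ))], occ)
      adv <- advancement_probability(ranks)
      advancement[[key]] <- cbind(meta[rep(1L, nrow(adv))], adv)
      ceiling_rows[[key]] <- cbind(meta, data.table::data.table(
        glass_ceiling = glass_ceiling_rank(ranks)))
      if (!is.null(cache)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(summaries[[key]], cache, row.names = FALSE)
      }
    }
  }
  list(group_summary = data.table::rbindlist(summaries, fill = TRUE),
       occupancy = data.table::rbindlist(occupancy),
       advancement = data.table::rbindlist(advancement),
       glass_ceiling = data.table::rbindlist(ceiling_rows))
}

#' Group-size by gossip sweep with extreme-rank Z-scores
#'
#' Varies the S-group size, sigma_S and the gossip count k over the
#' configured grids, runs `size_replicas` replicas per cell, pools the
#' stationary rank records across replicas and reports the top-5 and
#' bottom-5 Z-scores of the L-group's representation. Cells where one group
#' is empty have no defined Z-score and are recorded as missing.
#'
#' @inheritParams two_group_sweep
#' @param n_extreme number of extreme ranks for the Z-score (default 5).
#' @return A `data.table` with columns `n_small`, `n_large`, `sigma_small`,
#'   `sigma_large`, `relation`, `k`, `side`, `zscore`, `n_obs`, `seed`.
#' @export
group_size_sweep <- function(config = sweep_config(), n_extreme = 5L) {
  rows <- list()
  cell_id <- 0L
  for (relation in relations_of(config)) {
    for (ss in config$sigma_small_grid) {
      for (ns in config$n_small_grid) {
        for (k in config$gossip_grid) {
          cell_id <- cell_id + 1L
          sl <- sigma_relation(ss, relation)
          seed <- config$base_seed + 10000L * cell_id
          degenerate <- ns == 0L || ns == config$n_agents
          base <- data.table::data.table(
            n_small = ns, n_large = config$n_agents - ns,
            sigma_small = ss, sigma_large = sl, relation = relation,
            k = k, seed = seed)
          if (degenerate) {
            rows[[length(rows) + 1L]] <- cbind(
              base[rep(1L, 2L)],
              data.table::data.table(side = c("top", "bottom"),
                                     zscore = NA_real_, n_obs = NA_integer_))
            next
          }
          reps <- effective_replicas(config, config$size_replicas)
          params <- cell_params(config, ss, sl, ns, k, seed)
          runs <- run_replicas(params, reps,
                               stationary_window = config$stationary_window)
          ranks <- rank_records(runs, stationary = TRUE)
          n_obs <- nrow(unique(ranks[, .(replica, t)])) * n_extreme
          rows[[length(rows) + 1L]] <- cbind(
            base[rep(1L, 2L)],
            data.table::data.table(
              side = c("top", "bottom"),
              zscore = c(extreme_rank_zscore(ranks, n_extreme, "top"),
                         extreme_rank_zscore(ranks, n_extreme, "bottom")),
              n_obs = n_obs))
        }
      }
    }
  }
  data.table::rbindlist(rows)
}
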
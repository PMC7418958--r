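model_param_keys <- c("n_agents", "n_small", "n_large", "sigma_small",
                      "sigma_large", "noise_half_width", "gossip_count",
                      "same_group_prob", "esteem_bounds", "n_iterations",
                      "measure_every", "seed")

sweep_keys <- c("sigma_small_grid", "sigma_relation", "n_small_grid",
                "gossip_grid", "replicas", "size_replicas", "base_seed",
                "stationary_window", "scale_factor")

#' Load a run configuration from a YAML file
#'
#' The file may contain any [model_params()] field and any [sweep_config()]
#' field (optionally nested under `model:` and `sweep:` keys). Missing
#' fields take the study defaults (N = 40 split 20/20, delta = 0.2, k = 3,
#' same-group probability 0.5, bounds (-1, 1), 500,000 iterations measured
#' every 10,000); an empty file yields the full default configuration.
#' Unknown keys are rejected by name.
#'
#' @param path path to a YAML file.
#' @return A list with elements `params` ([model_params()]) and `sweep`
#'   ([sweep_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  flat <- c(raw[["model"]], raw[["sweep"]],
            raw[setdiff(names(raw), c("model", "sweep"))])
  unknown <- setdiff(names(flat), c(model_param_keys, sweep_keys))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  margs <- flat[names(flat) %in% model_param_keys]
  # n_large defaults to the complement when only n_small is given
  if (!is.null(margs$n_small) && is.null(margs$n_large)) {
    n <- if (is.null(margs$n_agents)) 40L else as.integer(margs$n_agents)
    margs$n_large <- n - as.integer(margs$n_small)
  }
  if (!is.null(margs$sigma_small) && is.null(margs$sigma_large)) {
    margs$sigma_large <- 1.5 * as.numeric(margs$sigma_small)
  }
  params <- do.call(model_params, margs)
  sargs <- flat[names(flat) %in% sweep_keys]
  sargs$n_agents <- params$n_agents
  sargs$noise_half_width <- params$noise_half_width
  sargs$gossip_count <- params$gossip_count
  sargs$same_group_prob <- params$same_group_prob
  sargs$measure_every <- params$measure_every
  sargs$n_iterations <- params$n_iterations
  sweep <- do.call(sweep_config, sargs)
  list(params = params, sweep = sweep)
}

#' Deterministic test states
#'
#' Small esteem states used throughout the unit tests and examples:
#' * `"zeros"` — the model's initial condition (all esteems 0);
#' * `"worked_example"` — a 3-agent state with `a[2,1] = 0.4`,
#'   `a[2,2] = -0.2` and `a[2,3] = 0.6`, whose influence and gossip updates
#'   from a neutral listener (credibility exactly 0.5) can be checked by
#'   hand;
#' * `"random_small"` — seeded uniform entries within the esteem bounds.
#'
#' @param kind one of `"zeros"`, `"worked_example"`, `"random_small"`.
#' @param seed seed for `"random_small"`.
#' @param n_agents population size for `"zeros"`/`"random_small"`.
#' @param params a [model_params()] used for the bounds and group split of
#'   `"random_small"`; defaults to a small two-group setup.
#' @return A list with elements `state` (an `esteem_state`) and `groups`
#'   (a [group_assignment()]).
#' @export
fixture_state <- function(kind = c("zeros", "worked_example", "random_small"),
                          seed = 1L, n_agents = 4L, params = NULL) {
  kind <- match.arg(kind)
  if (kind == "worked_example") n_agents <- 3L
  if (is.null(params)) {
    ns <- n_agents %/% 2L
    params <- model_params(n_agents = n_agents, n_small = ns,
                           n_large = n_agents - ns, sigma_small = 0.1,
                           sigma_large = 0.15, n_iterations = 0L,
                           measure_every = 1L, seed = seed)
  }
  groups <- group_assignment(params)
  state <- esteem_state(n_agents)
  if (kind == "worked_example") {
    state$a[2, 1] <- 0.4
    state$a[2, 2] <- -0.2
    state$a[2, 3] <- 0.6
  } else if (kind == "random_small") {
    set.seed(seed)
    state$a <- matrix(stats::runif(n_agents^2, params$esteem_bounds[1],
                                   params$esteem_bounds[2]),
                      n_agents, n_agents)
  }
  list(state = state, groups = groups)
}

format_numeric_cols <- function(df, digits = 10) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA,
                         format(df[[nm]], digits = digits, trim = TRUE,
                                scientific = FALSE))
    }
  }
  df
}

#' Write result tables with a digest manifest
#'
#' Writes each table of a named list as `<name>.csv` under `out_dir`
#' (numeric columns serialised at 10 significant digits so digests are
#' platform-stable) plus a `manifest.json` recording the configuration echo,
#' per-file MD5 digests and timestamps.
#'
#' @param tables named list of data.frames, or a single data.frame (written
#'   as `result.csv`), or the list returned by [two_group_sweep()].
#' @param out_dir output directory, created if needed.
#' @param config_echo optional list stored verbatim in the manifest.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(tables, out_dir, config_echo = NULL) {
  if (is.data.frame(tables)) tables <- list(result = tables)
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(format_numeric_cols(as.data.frame(tables[[nm]])),
                     path, row.names = FALSE, quote = FALSE, na = "")
    files[[nm]] <- list(file = basename(path),
                        md5 = unname(tools::md5sum(path)),
                        rows = nrow(tables[[nm]]))
  }
  manifest <- list(package = "leviathan",
                   version = as.character(utils::packageVersion("leviathan")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config_echo,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Long-format CSV serialisation of an esteem snapshot series
#'
#' One row per (snapshot, listener, target): columns `replica`, `t`, `i`,
#' `j`, `esteem`. [read_series_csv()] reconstructs the matrices; the
#' round trip is exact to the serialised precision.
#'
#' @param series a `snapshot_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  n <- series$params$n_agents
  dt <- data.table::rbindlist(lapply(seq_along(series$times), function(m) {
    data.table::data.table(replica = series$replica_id,
                           t = series$times[m],
                           i = rep(seq_len(n), times = n),
                           j = rep(seq_len(n), each = n),
                           esteem = as.vector(series$snapshots[[m]]))
  }))
  dt$esteem <- format(dt$esteem, digits = 10, trim = TRUE, scientific = FALSE)
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @return For `read_series_csv`: a list with `times` and `snapshots`.
#' @export
read_series_csv <- function(path) {
  dt <- data.table::fread(path)
  times <- sort(unique(dt$t))
  n <- max(dt$i)
  snapshots <- lapply(times, function(tt) {
    sub <- dt[dt$t == tt, ]
    data.table::setorder(sub, j, i)
    matrix(sub$esteem, n, n)
  })
  list(times = as.integer(times), snapshots = snapshots)
}
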
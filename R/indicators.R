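#' @import data.table
NULL

# population (not sample) standard deviation: descriptive statistic over the
# whole group
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Reputation of every agent at one snapshot
#'
#' An agent's reputation is the mean esteem accorded to it by all the other
#' agents: the column mean of the esteem matrix with the diagonal
#' (self-esteem) excluded.
#'
#' @param snapshot a square esteem matrix (or an `esteem_state`).
#' @return Numeric vector of per-agent reputations.
#' @export
reputation_vector <- function(snapshot) {
  a <- if (inherits(snapshot, "esteem_state")) snapshot$a else snapshot
  n <- nrow(a)
  if (is.null(n) || n < 2L || ncol(a) != n) {
    stop("reputation requires a square esteem matrix with at least 2 agents",
         call. = FALSE)
  }
  (colSums(a) - diag(a)) / (n - 1)
}

#' Mean of a per-agent quantity within one group
#'
#' @param values per-agent numeric vector (e.g. reputations, or the matrix
#'   diagonal for self-esteems).
#' @param groups a [group_assignment()].
#' @param which `"S"` or `"L"`.
#' @return The arithmetic mean over the group's members.
#' @export
group_mean <- function(values, groups, which = c("S", "L")) {
  which <- match.arg(which)
  sel <- groups$labels == which
  if (!any(sel)) stop("group ", which, " is empty", call. = FALSE)
  mean(values[sel])
}

#' Variation coefficient of a per-agent quantity
#'
#' Population standard deviation divided by the magnitude of the mean. The
#' absolute value in the denominator matters here because group mean
#' self-esteems are typically negative in this model; a signed coefficient
#' would flip the ordering between groups.
#'
#' @param values numeric vector (one group's values).
#' @return Non-negative real; errors when the mean is zero.
#' @export
variation_coefficient <- function(values) {
  m <- mean(values)
  if (m == 0) {
    stop("variation coefficient undefined for zero mean", call. = FALSE)
  }
  pop_sd(values) / abs(m)
}

#' Consensual stratification of a group
#'
#' The population standard deviation of the group's reputations: how strongly
#' the population's shared view differentiates status within the group.
#'
#' @inheritParams reputation_vector
#' @param groups a [group_assignment()].
#' @param which `"S"` or `"L"`.
#' @return Non-negative real.
#' @export
consensual_stratification <- function(snapshot, groups, which = c("S", "L")) {
  which <- match.arg(which)
  rep <- reputation_vector(snapshot)
  sel <- groups$labels == which
  if (sum(sel) < 2L) {
    stop("stratification requires at least 2 group members", call. = FALSE)
  }
  pop_sd(rep[sel])
}

#' Social ranks at one snapshot
#'
#' Rank 1 is the best (highest) reputation, rank N the worst. Exact ties are
#' broken by ascending agent index; with continuous noise ties have measure
#' zero, and the rule keeps the noiseless degenerate case deterministic.
#'
#' @inheritParams reputation_vector
#' @return Integer vector of ranks, a permutation of 1..N.
#' @export
rank_vector <- function(snapshot) {
  rep <- reputation_vector(snapshot)
  n <- length(rep)
  r <- integer(n)
  r[order(-rep, seq_len(n))] <- seq_len(n)
  r
}

#' Long table of social ranks over the stationary window
#'
#' @param series a `snapshot_series` or a list of them (pooled replicas).
#' @param stationary when `TRUE` (default) only the trailing
#'   stationary-window snapshots are included.
#' @return A `data.table` with columns `replica`, `t`, `agent`, `group`,
#'   `rank`; at each `(replica, t)` the ranks form a permutation of 1..N.
#' @export
rank_records <- function(series, stationary = TRUE) {
  if (inherits(series, "snapshot_series")) series <- list(series)
  out <- lapply(series, function(s) {
    idx <- if (stationary) stationary_indices(s) else seq_along(s$times)
    n <- s$params$n_agents
    data.table::rbindlist(lapply(idx, function(m) {
      data.table::data.table(
        replica = s$replica_id,
        t = s$times[m],
        agent = seq_len(n),
        group = s$groups$labels,
        rank = rank_vector(s$snapshots[[m]])
      )
    }))
  })
  data.table::rbindlist(out)
}

#' Probability that each rank is occupied by each group
#'
#' The fraction of pooled (snapshot, replica) observations in which rank r is
#' held by an S-group (resp. L-group) agent; for two-group runs the two
#' probabilities sum to 1 at every rank.
#'
#' @param records a rank table from [rank_records()] (possibly pooled).
#' @return A `data.table` with columns `rank`, `group`, `probability`,
#'   `n_obs`.
#' @export
occupancy_probability <- function(records) {
  records <- data.table::as.data.table(records)
  tot <- records[, .(n_obs = .N), by = rank]
  occ <- records[, .(count = .N), by = .(rank, group)]
  occ <- merge(occ, tot, by = "rank")
  occ[, probability := count / n_obs]
  data.table::setorder(occ, rank, group)
  occ[, .(rank, group, probability, n_obs)]
}

#' Glass-ceiling threshold: best rank ever attained by the L-group
#'
#' The minimum (best) rank held by any L-group agent over the pooled
#' stationary-window observations. In the model's typical two-group regime
#' this sits well below rank 1: a band of top ranks the more open-minded
#' group never enters.
#'
#' @inheritParams occupancy_probability
#' @return Integer rank.
#' @export
glass_ceiling_rank <- function(records) {
  records <- data.table::as.data.table(records)
  lr <- records[group == "L", rank]
  if (length(lr) == 0L) stop("no L-group observations", call. = FALSE)
  as.integer(min(lr))
}

#' Rank-advancement probability by group and current rank
#'
#' For each group g and rank r, the fraction of observations in which an
#' agent of group g holding rank r at one measurement holds rank <= r (no
#' worse) at the next measurement. "Next" means the next snapshot at the
#' measurement cadence, not the next micro-iteration.
#'
#' @inheritParams occupancy_probability
#' @return A `data.table` with columns `group`, `rank`, `probability`,
#'   `n_obs`; (group, rank) cells never observed are absent.
#' @export
advancement_probability <- function(records) {
  records <- data.table::as.data.table(records)
  data.table::setorder(records, replica, agent, t)
  records[, next_rank := data.table::shift(rank, type = "lead"),
          by = .(replica, agent)]
  obs <- records[!is.na(next_rank)]
  if (nrow(obs) == 0L) {
    stop("advancement requires at least 2 snapshots per replica",
         call. = FALSE)
  }
  out <- obs[, .(probability = mean(next_rank <= rank), n_obs = .N),
             by = .(group, rank)]
  data.table::setorder(out, group, rank)
  out[]
}

#' Z-score of the L-group's presence in the extreme ranks
#'
#' Under proportional representation the expected share of the top-`n_extreme`
#' (or bottom-`n_extreme`) rank slots held by L-group agents is q = N_L / N.
#' Over all pooled (snapshot, replica) observations, with n extreme slots in
#' total and X of them held by L agents, the statistic is the standardised
#' binomial deviation
#' \deqn{Z = (X - n q) / \sqrt{n q (1 - q)}.}
#' Negative top-rank Z (and positive bottom-rank Z) indicate the L-group is
#' under-represented at the top and over-represented at the bottom.
#'
#' @inheritParams occupancy_probability
#' @param n_extreme number of extreme ranks (default 5).
#' @param side `"top"` (ranks 1..n_extreme) or `"bottom"` (the n_extreme
#'   worst ranks).
#' @return A single real Z-score.
#' @export
extreme_rank_zscore <- function(records, n_extreme = 5L,
                                side = c("top", "bottom")) {
  side <- match.arg(side)
  records <- data.table::as.data.table(records)
  n_agents <- max(records$rank)
  first_obs <- records[replica == records$replica[1] & t == records$t[1]]
  q <- mean(first_obs$group == "L")
  if (q <= 0 || q >= 1) {
    stop("Z-score undefined when the L-group fraction is 0 or 1",
         call. = FALSE)
  }
  extreme <- if (side == "top") records[rank <= n_extreme]
             else records[rank > n_agents - n_extreme]
  n_snapshots <- nrow(unique(records[, .(replica, t)]))
  n_slots <- n_extreme * n_snapshots
  x <- sum(extreme$group == "L")
  (x - n_slots * q) / sqrt(n_slots * q * (1 - q))
}

#' Group-level indicator summaries over time
#'
#' For every snapshot and group: mean reputation, mean self-esteem, the
#' variation coefficients of self-esteem and of reputation, and the
#' population standard deviation of reputation (consensual stratification).
#' Variation coefficients are `NA` when the corresponding group mean is zero
#' (as at the all-zero initial state).
#'
#' @param series a `snapshot_series` or list of them.
#' @param stationary restrict to the trailing stationary window?
#' @return A `data.table` with columns `replica`, `t`, `group`,
#'   `mean_reputation`, `mean_self_esteem`, `cv_self_esteem`,
#'   `cv_reputation`, `sd_reputation`.
#' @export
group_summary <- function(series, stationary = FALSE) {
  if (inherits(series, "snapshot_series")) series <- list(series)
  safe_cv <- function(x) if (mean(x) == 0) NA_real_ else variation_coefficient(x)
  out <- lapply(series, function(s) {
    idx <- if (stationary) stationary_indices(s) else seq_along(s$times)
    labs <- s$groups$labels
    present <- unique(labs)
    data.table::rbindlist(lapply(idx, function(m) {
      a <- s$snapshots[[m]]
      rep <- reputation_vector(a)
      se <- diag(a)
      data.table::rbindlist(lapply(present, function(g) {
        sel <- labs == g
        data.table::data.table(
          replica = s$replica_id,
          t = s$times[m],
          group = g,
          mean_reputation = mean(rep[sel]),
          mean_self_esteem = mean(se[sel]),
          cv_self_esteem = safe_cv(se[sel]),
          cv_reputation = safe_cv(rep[sel]),
          sd_reputation = pop_sd(rep[sel])
        )
      }))
    }))
  })
  data.table::rbindlist(out)
}
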
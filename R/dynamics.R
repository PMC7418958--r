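#' Credibility of a speaker in the eyes of a listener
#'
#' The logistic influence function: the weight a listener gives to what a
#' speaker says is a smooth threshold function of the listener's perceived
#' relative status, i.e. the difference between the esteem the listener holds
#' for the speaker and the listener's self-esteem,
#' \deqn{p = \frac{1}{1 + e^{-(a_{ij} - a_{ii})/\sigma}}.}
#' Small `sigma` means credibility switches sharply around status parity;
#' large `sigma` means everyone is roughly equally credible (p near 0.5).
#'
#' @param esteem_of_speaker the listener's esteem for the speaker, a_ij.
#' @param self_esteem the listener's self-esteem, a_ii.
#' @param sigma the listener's open-mindedness (> 0).
#' @return Credibility in (0, 1); vectorised over the esteem arguments.
#' @examples
#' credibility(0.1, 0, sigma = 3)     # ~0.508: near-indifferent listener
#' credibility(-0.1, 0, sigma = 0.05) # ~0.119: status-sensitive listener
#' @export
credibility <- function(esteem_of_speaker, self_esteem, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("sigma must be a positive real", call. = FALSE)
  }
  stopifnot(all(is.finite(esteem_of_speaker)), all(is.finite(self_esteem)))
  1 / (1 + exp(-(esteem_of_speaker - self_esteem) / sigma))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# One uniform deviate, then a 0-based index in 0..n-1. Mirrors the compiled
# engine exactly (same rejection behaviour as runif(1)), which is what makes
# the reference/compiled oracle comparison entry-wise exact.
draw_index <- function(n) {
  k <- floor(stats::runif(1) * n)
  if (k >= n) k <- n - 1
  as.integer(k) + 1L
}

draw_noise <- function(delta) {
  -delta + 2 * delta * stats::runif(1)
}

#' Directed influence step (reference implementation)
#'
#' Agent `listener` (i) hears speaker j report j's esteem of i and of j
#' itself, each perturbed by uniform noise on (-delta, +delta), and moves its
#' own self-esteem `a[i,i]` and its esteem of the speaker `a[i,j]` toward the
#' reported values with weight p = [credibility()] computed from the
#' pre-update values. Both updated entries are clipped to the esteem bounds.
#' Only row i changes, and within it only columns i and j.
#'
#' This R implementation is deliberately simple and serves as the readable
#' reference for the compiled engine; both consume the random stream
#' identically.
#'
#' @param state an `esteem_state`.
#' @param listener,speaker distinct agent indices (listener is updated).
#' @param params a [model_params()] object.
#' @param groups a [group_assignment()].
#' @return The updated `esteem_state`.
#' @export
influence_step <- function(state, listener, speaker, params, groups) {
  i <- as.integer(listener)
  j <- as.integer(speaker)
  if (i == j) stop("listener and speaker must differ", call. = FALSE)
  a <- state$a
  lo <- params$esteem_bounds[1]
  hi <- params$esteem_bounds[2]
  d <- params$noise_half_width
  p <- credibility(a[i, j], a[i, i], groups$sigma[i])
  a[i, i] <- clip(a[i, i] + p * (a[j, i] - a[i, i] + draw_noise(d)), lo, hi)
  a[i, j] <- clip(a[i, j] + p * (a[j, j] - a[i, j] + draw_noise(d)), lo, hi)
  state$a <- a
  state
}

#' Directed gossip step (reference implementation)
#'
#' The speaker j transmits its esteems about `gossip_count` third parties to
#' the listener i. Credibility p is computed once per directed call (it is
#' indexed by the pair, not by the gossip target) and reused for all k
#' updates. Each repetition draws a target z uniformly from the agents other
#' than i and j (independently, so targets may repeat) and a fresh noise
#' term, then moves `a[i,z]` toward the reported `a[j,z]` with weight p,
#' clipping to bounds.
#'
#' @inheritParams influence_step
#' @return The updated `esteem_state`.
#' @export
gossip_step <- function(state, listener, speaker, params, groups) {
  i <- as.integer(listener)
  j <- as.integer(speaker)
  if (i == j) stop("listener and speaker must differ", call. = FALSE)
  k <- params$gossip_count
  if (k == 0L) return(state)
  n <- nrow(state$a)
  if (n < 3L) {
    stop("gossip requires at least 3 agents (no valid third party)",
         call. = FALSE)
  }
  a <- state$a
  lo <- params$esteem_bounds[1]
  hi <- params$esteem_bounds[2]
  d <- params$noise_half_width
  p <- credibility(a[i, j], a[i, i], groups$sigma[i])
  cand <- seq_len(n)[-c(i, j)]
  for (rep in seq_len(k)) {
    z <- cand[draw_index(n - 2L)]
    u <- draw_noise(d)
    a[i, z] <- clip(a[i, z] + p * (a[j, z] - a[i, z] + u), lo, hi)
  }
  state$a <- a
  state
}

#' Draw an interaction partner for a focal agent
#'
#' With probability `same_group_prob` the partner is drawn uniformly from the
#' focal agent's own group (excluding the agent itself), otherwise uniformly
#' from the other group. If the targeted pool is empty (the focal agent is
#' its group's only member, or one group is empty as in single-group
#' baselines) the other pool is used, so a valid partner j != i is always
#' returned for populations of at least two agents.
#'
#' @param i focal agent index.
#' @param groups a [group_assignment()].
#' @param params a [model_params()] object.
#' @return A partner index j != i.
#' @export
select_partner <- function(i, groups, params) {
  i <- as.integer(i)
  same <- stats::runif(1) < params$same_group_prob
  own <- groups$labels[i]
  mem_own <- setdiff(which(groups$labels == own), i)
  mem_oth <- which(groups$labels != own)
  pool <- if (same) mem_own else mem_oth
  if (length(pool) == 0L) pool <- if (same) mem_oth else mem_own
  if (length(pool) == 0L) stop("no eligible partner", call. = FALSE)
  pool[draw_index(length(pool))]
}

#' One full dyadic encounter (reference implementation)
#'
#' Applies, in order and sequentially (each step reading the state left by
#' the previous one): influence(i, j), influence(j, i), gossip(i, j),
#' gossip(j, i).
#'
#' @inheritParams influence_step
#' @param i,j distinct agent indices.
#' @return The updated `esteem_state`.
#' @export
interaction_step <- function(state, i, j, params, groups) {
  state <- influence_step(state, i, j, params, groups)
  state <- influence_step(state, j, i, params, groups)
  state <- gossip_step(state, i, j, params, groups)
  state <- gossip_step(state, j, i, params, groups)
  state
}

#' One model iteration (reference implementation)
#'
#' One iteration is `floor(n_agents / 2)` encounter executions, so each agent
#' interacts once on average: repeatedly draw a focal agent i uniformly (with
#' replacement across executions), a partner j via [select_partner()], and
#' run [interaction_step()]. The iteration clock advances by 1.
#'
#' @inheritParams influence_step
#' @return The updated `esteem_state` with `t` incremented.
#' @export
run_iteration <- function(state, params, groups) {
  n <- params$n_agents
  for (m in seq_len(n %/% 2L)) {
    i <- draw_index(n)
    j <- select_partner(i, groups, params)
    state <- interaction_step(state, i, j, params, groups)
  }
  state$t <- state$t + 1L
  state
}
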
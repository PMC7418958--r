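#' Model parameters for the influence-Leviathan dynamics
#'
#' Collects every dynamical constant of the two-group model in one validated
#' object. The population of `n_agents` agents is split into an S-group
#' (`n_small` agents with small open-mindedness `sigma_small`) and an L-group
#' (`n_large` agents with large open-mindedness `sigma_large`). Small sigma
#' makes an agent's credibility assignments depend sharply on perceived
#' relative status; large sigma makes all interlocutors near-equally credible.
#'
#' @param n_agents total number of agents N.
#' @param n_small number of S-group agents.
#' @param n_large number of L-group agents; defaults to `n_agents - n_small`.
#'   A single-group (baseline) population is expressed as `n_large = 0`.
#' @param sigma_small open-mindedness of the S-group (logistic slope
#'   parameter, dimensionless, > 0).
#' @param sigma_large open-mindedness of the L-group; must exceed
#'   `sigma_small` whenever both groups are non-empty.
#' @param noise_half_width half-width delta of the uniform noise added to
#'   every communicated esteem (>= 0).
#' @param gossip_count number k of third parties the speaker gossips about
#'   per directed encounter (>= 0).
#' @param same_group_prob probability that a partner is drawn from the focal
#'   agent's own group.
#' @param esteem_bounds length-2 numeric, the (min, max) bounds esteems are
#'   clipped to after every update.
#' @param n_iterations simulation horizon in iterations; one iteration is
#'   `floor(n_agents / 2)` pair interactions.
#' @param measure_every snapshot cadence in iterations.
#' @param seed integer seed for the replica's random number stream.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(n_agents = 40, n_small = 20, sigma_small = 0.1,
#'                   sigma_large = 0.15, n_iterations = 1000,
#'                   measure_every = 100, seed = 1)
#' p
#' @export
model_params <- function(n_agents = 40L,
                         n_small = 20L,
                         n_large = n_agents - n_small,
                         sigma_small = 0.1,
                         sigma_large = 1.5 * sigma_small,
                         noise_half_width = 0.2,
                         gossip_count = 3L,
                         same_group_prob = 0.5,
                         esteem_bounds = c(-1, 1),
                         n_iterations = 500000L,
                         measure_every = 10000L,
                         seed = 1L) {
  p <- list(
    n_agents = as.integer(n_agents),
    n_small = as.integer(n_small),
    n_large = as.integer(n_large),
    sigma_small = as.numeric(sigma_small),
    sigma_large = as.numeric(sigma_large),
    noise_half_width = as.numeric(noise_half_width),
    gossip_count = as.integer(gossip_count),
    same_group_prob = as.numeric(same_group_prob),
    esteem_bounds = as.numeric(esteem_bounds),
    n_iterations = as.integer(n_iterations),
    measure_every = as.integer(measure_every),
    seed = as.integer(seed)
  )
  class(p) <- "model_params"
  validate_model_params(p)
}

validate_model_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (p$n_agents < 2L) {
    stop("n_agents must be at least 2", call. = FALSE)
  }
  if (p$n_small < 0L || p$n_large < 0L || p$n_small + p$n_large != p$n_agents) {
    stop("n_small + n_large must equal n_agents (got ", p$n_small, " + ",
         p$n_large, " != ", p$n_agents, ")", call. = FALSE)
  }
  if (!is.finite(p$sigma_small) || p$sigma_small <= 0) {
    stop("sigma_small must be a positive real", call. = FALSE)
  }
  if (!is.finite(p$sigma_large) || p$sigma_large <= 0) {
    stop("sigma_large must be a positive real", call. = FALSE)
  }
  if (p$n_small > 0L && p$n_large > 0L && p$sigma_small >= p$sigma_large) {
    stop("in two-group runs sigma_small must be < sigma_large", call. = FALSE)
  }
  if (p$noise_half_width < 0) {
    stop("noise_half_width must be >= 0", call. = FALSE)
  }
  if (p$gossip_count < 0L) {
    stop("gossip_count must be >= 0", call. = FALSE)
  }
  if (p$gossip_count > 0L && p$n_agents < 3L) {
    stop("gossip requires at least 3 agents (no valid third party otherwise)",
         call. = FALSE)
  }
  if (p$same_group_prob < 0 || p$same_group_prob > 1) {
    stop("same_group_prob must lie in [0, 1]", call. = FALSE)
  }
  if (length(p$esteem_bounds) != 2L || p$esteem_bounds[1] >= p$esteem_bounds[2]) {
    stop("esteem_bounds must be an ordered pair (min < max)", call. = FALSE)
  }
  if (p$n_iterations < 0L) stop("n_iterations must be >= 0", call. = FALSE)
  if (p$measure_every < 1L) stop("measure_every must be >= 1", call. = FALSE)
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Influence-Leviathan model parameters\n")
  cat(sprintf("  agents: %d (S-group %d at sigma=%g, L-group %d at sigma=%g)\n",
              x$n_agents, x$n_small, x$sigma_small, x$n_large, x$sigma_large))
  cat(sprintf("  noise delta=%g, gossip k=%d, same-group prob=%g\n",
              x$noise_half_width, x$gossip_count, x$same_group_prob))
  cat(sprintf("  bounds [%g, %g], horizon %d iterations, measure every %d, seed %d\n",
              x$esteem_bounds[1], x$esteem_bounds[2], x$n_iterations,
              x$measure_every, x$seed))
  invisible(x)
}

#' Group assignment derived from model parameters
#'
#' Labels the first `n_small` agents "S" and the remaining `n_large` agents
#' "L", and records each agent's open-mindedness. Contact is uniform across
#' groups, so the ordering of labels is immaterial to the dynamics.
#'
#' @param params a [model_params()] object.
#' @return An object of class `group_assignment` with fields `labels`
#'   (character vector over "S"/"L") and `sigma` (per-agent open-mindedness).
#' @export
group_assignment <- function(params) {
  validate_model_params(params)
  labels <- c(rep("S", params$n_small), rep("L", params$n_large))
  g <- list(
    labels = labels,
    sigma = ifelse(labels == "S", params$sigma_small, params$sigma_large)
  )
  class(g) <- "group_assignment"
  g
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("Group assignment: %d S (sigma %s), %d L (sigma %s)\n",
              sum(x$labels == "S"),
              format(unique(x$sigma[x$labels == "S"])[1]),
              sum(x$labels == "L"),
              format(unique(x$sigma[x$labels == "L"])[1])))
  invisible(x)
}

#' Zero-initialised esteem state
#'
#' Every agent starts neutral: all self-esteems and esteems of others are 0.
#'
#' @param n_agents side of the square esteem matrix.
#' @return An object of class `esteem_state`: list with the esteem matrix `a`
#'   (entry `a[i, j]` = esteem agent i holds for agent j, diagonal =
#'   self-esteem) and the iteration clock `t`.
#' @export
esteem_state <- function(n_agents) {
  s <- list(a = matrix(0, n_agents, n_agents), t = 0L)
  class(s) <- "esteem_state"
  s
}

#' @export
print.esteem_state <- function(x, ...) {
  cat(sprintf("Esteem state: %d agents at iteration %d (mean esteem %.4f)\n",
              nrow(x$a), x$t, mean(x$a)))
  invisible(x)
}
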
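test_that("credibility matches the logistic influence function", {
  # anchors computed from p = 1/(1 + exp(-d/sigma))
  expect_equal(credibility(0, 0, 3), 0.5)
  expect_equal(credibility(0, 0, 0.01), 0.5)
  expect_equal(round(credibility(0.1, 0, 3), 1), 0.5)
  expect_equal(round(credibility(-0.1, 0, 3), 1), 0.5)
  expect_equal(round(credibility(-0.1, 0, 0.05), 1), 0.1)
  expect_equal(round(credibility(0.1, 0, 0.05), 4), 0.8808)
  # offset invariance: only the difference matters
  expect_equal(credibility(0.4, 0.3, 0.05), credibility(0.1, 0, 0.05))
})

test_that("credibility algebra: symmetry, monotonicity, flat limit", {
  for (sigma in c(0.05, 0.1, 0.5, 3)) {
    d <- seq(-2, 2, by = 0.25)
    expect_equal(credibility(d, 0, sigma) + credibility(-d, 0, sigma),
                 rep(1, length(d)))
    expect_true(all(diff(credibility(d, 0, sigma)) > 0))
  }
  expect_lt(abs(credibility(0.1, 0, 1e3) - 0.5), 1e-3)
  expect_error(credibility(0, 0, 0), "sigma")
  expect_error(credibility(0, 0, -1), "sigma")
})

test_that("influence step reproduces the hand-computed update", {
  fx <- fixture_state("worked_example")
  params <- quiet_params(3L)
  # listener 1 is neutral (a11 = a12 = 0) so p = 0.5 exactly for any sigma;
  # speaker 2 holds a21 = 0.4 about the listener and a22 = -0.2 about itself
  set.seed(1)
  st <- influence_step(fx$state, 1, 2, params, fx$groups)
  expect_equal(st$a[1, 1], 0.2)
  expect_equal(st$a[1, 2], -0.1)
  # only row 1, columns 1 and 2 changed
  changed <- which(st$a != fx$state$a, arr.ind = TRUE)
  expect_true(all(changed[, "row"] == 1))
  expect_setequal(changed[, "col"], c(1, 2))
  expect_error(influence_step(fx$state, 2, 2, params, fx$groups), "differ")
})

test_that("influence updates are clipped to the esteem bounds", {
  params <- quiet_params(3L, sigma_small = 1e-3, sigma_large = 2e-3)
  fx <- fixture_state("zeros", n_agents = 3L, params = params)
  st <- fx$state
  # listener holds the speaker above itself by 0.05 >> sigma, so p ~ 1;
  # the speaker's (raw, unclipped) report would push self-esteem to 1.15
  st$a[1, 1] <- 0.95
  st$a[1, 2] <- 1
  st$a[2, 1] <- 1.15
  set.seed(1)
  out <- influence_step(st, 1, 2, params, fx$groups)
  expect_equal(out$a[1, 1], 1)
})

test_that("zero state with zero noise is a fixed point of every update", {
  params <- quiet_params(4L, n_agents = 4L, gossip_count = 2L)
  fx <- fixture_state("zeros", n_agents = 4L, params = params)
  set.seed(3)
  st <- interaction_step(fx$state, 1, 3, params, fx$groups)
  expect_equal(st$a, fx$state$a)
  set.seed(3)
  st <- run_iteration(fx$state, params, fx$groups)
  expect_equal(st$a, fx$state$a)
  expect_equal(st$t, 1L)
})

test_that("gossip step follows the propagation rule", {
  fx <- fixture_state("worked_example")
  params <- quiet_params(3L, gossip_count = 1L)
  # with 3 agents the single gossip target is forced: z = 3; listener 1 is
  # neutral so p = 0.5, and a13 moves halfway to a23 = 0.6
  set.seed(1)
  st <- gossip_step(fx$state, 1, 2, params, fx$groups)
  expect_equal(st$a[1, 3], 0.3)
  # k = 0 leaves the state untouched and consumes no esteem change
  params0 <- quiet_params(3L, gossip_count = 0L)
  st0 <- gossip_step(fx$state, 1, 2, params0, fx$groups)
  expect_identical(st0$a, fx$state$a)
  # identical listener and speaker rows: zero difference, zero update
  params2 <- quiet_params(4L, n_agents = 4L, gossip_count = 3L)
  fx2 <- fixture_state("zeros", n_agents = 4L, params = params2)
  fx2$state$a[1, ] <- c(0.1, 0.2, 0.3, 0.4)
  fx2$state$a[2, ] <- c(0.1, 0.2, 0.3, 0.4)
  set.seed(9)
  st2 <- gossip_step(fx2$state, 1, 2, params2, fx2$groups)
  expect_equal(st2$a, fx2$state$a)
})

test_that("gossip with fewer than 3 agents is a configuration error", {
  p2 <- model_params(n_agents = 2L, n_small = 1L, sigma_small = 0.1,
                     sigma_large = 0.15, gossip_count = 0L,
                     n_iterations = 10L, measure_every = 5L)
  g2 <- group_assignment(p2)
  st <- esteem_state(2L)
  p2$gossip_count <- 1L  # bypass constructor validation to hit the step check
  expect_error(gossip_step(st, 1, 2, p2, g2), "3 agents")
  expect_error(model_params(n_agents = 2L, n_small = 1L, sigma_small = 0.1,
                            sigma_large = 0.15, gossip_count = 1L),
               "3 agents")
})

test_that("partner selection respects groups, excludes self, mixes at 0.5", {
  params <- tiny_params(40L, n_small = 20L)
  groups <- group_assignment(params)
  set.seed(11)
  n_draws <- 1e5
  focal <- 3L  # an S agent
  js <- vapply(seq_len(n_draws), function(...) {
    select_partner(focal, groups, params)
  }, integer(1))
  expect_true(all(js != focal))
  frac_same <- mean(groups$labels[js] == "S")
  se <- sqrt(0.25 / n_draws)
  expect_lt(abs(frac_same - 0.5), 3 * se)
})

test_that("degenerate groups fall back to the other pool", {
  # single-member own group: the same-group coin must still yield j != i
  p1 <- model_params(n_agents = 5L, n_small = 1L, sigma_small = 0.1,
                     sigma_large = 0.15, n_iterations = 10L,
                     measure_every = 5L)
  g1 <- group_assignment(p1)
  set.seed(5)
  js <- vapply(1:500, function(...) select_partner(1L, g1, p1), integer(1))
  expect_true(all(js != 1L))
  expect_true(all(g1$labels[js] == "L"))
  # empty L group (single-group baseline): partner uniform over all != i
  p0 <- model_params(n_agents = 6L, n_small = 6L, n_large = 0L,
                     sigma_small = 0.1, sigma_large = 1,
                     n_iterations = 10L, measure_every = 5L)
  g0 <- group_assignment(p0)
  set.seed(6)
  js <- vapply(1:2000, function(...) select_partner(2L, g0, p0), integer(1))
  expect_true(all(js != 2L))
  expect_setequal(unique(js), setdiff(1:6, 2L))
})

test_that("an encounter chains its four sub-steps sequentially", {
  fx <- fixture_state("worked_example")
  params <- quiet_params(3L, gossip_count = 0L)
  set.seed(2)
  st <- interaction_step(fx$state, 1, 2, params, fx$groups)
  # hand-chained expectation (delta = 0, k = 0):
  # influence(1,2): p = 0.5 -> a11 = 0.2, a12 = -0.1
  # influence(2,1): p2 = 1/(1+exp(-(a21 - a22)/sigma_2)), sigma_2 = 0.15
  p2 <- 1 / (1 + exp(-(0.4 - (-0.2)) / 0.15))
  a22 <- -0.2 + p2 * (-0.1 - (-0.2))
  a21 <- 0.4 + p2 * (0.2 - 0.4)
  expect_equal(st$a[1, 1], 0.2)
  expect_equal(st$a[1, 2], -0.1)
  expect_equal(st$a[2, 2], a22)
  expect_equal(st$a[2, 1], a21)
  # with k = 0 rows other than i and j are untouched
  expect_equal(st$a[3, ], fx$state$a[3, ])
})

test_that("one iteration advances the clock and stays deterministic", {
  params <- tiny_params(6L)
  groups <- group_assignment(params)
  st <- esteem_state(6L)
  set.seed(99)
  s1 <- run_iteration(st, params, groups)
  set.seed(99)
  s2 <- run_iteration(st, params, groups)
  expect_identical(s1$a, s2$a)
  expect_equal(s1$t, 1L)
})

test_that("compiled and reference engines agree entry-wise", {
  params <- tiny_params(4L, n_iterations = 20L, measure_every = 5L,
                        seed = 31L)
  a <- run_simulation(params, engine = "compiled")
  b <- run_simulation(params, engine = "reference")
  expect_identical(a$times, b$times)
  expect_identical(a$snapshots, b$snapshots)
})
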
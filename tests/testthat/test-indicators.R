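make_records <- function(ranks_by_time, labels) {
  # ranks_by_time: list of integer rank vectors (one per snapshot)
  data.table::rbindlist(lapply(seq_along(ranks_by_time), function(m) {
    data.table::data.table(replica = 1L, t = m, agent = seq_along(labels),
                           group = labels, rank = ranks_by_time[[m]])
  }))
}

test_that("reputation averages the esteem of all other agents", {
  expect_equal(reputation_vector(matrix(0, 3, 3)), rep(0, 3))
  a <- matrix(0, 3, 3)
  a[1, 2] <- 0.2
  a[3, 2] <- 0.4
  a[2, 2] <- 0.9  # self-esteem must be excluded
  expect_equal(reputation_vector(a)[2], 0.3)
  cmat <- matrix(0.25, 4, 4)
  diag(cmat) <- -1
  expect_equal(reputation_vector(cmat), rep(0.25, 4))
  expect_error(reputation_vector(matrix(0, 1, 1)), "2 agents")
})

test_that("group means and variation coefficients behave as defined", {
  p <- tiny_params(4L)
  g <- group_assignment(p)
  expect_equal(group_mean(c(0.7, 0.7, -1, -1), g, "S"), 0.7)
  expect_equal(group_mean(c(0, 0, -0.2, -0.4), g, "L"), -0.3)
  p1 <- model_params(n_agents = 3L, n_small = 1L, sigma_small = 0.1,
                     sigma_large = 0.15, n_iterations = 1L,
                     measure_every = 1L)
  g1 <- group_assignment(p1)
  expect_equal(group_mean(c(0.42, 0, 0), g1, "S"), 0.42)
  p0 <- model_params(n_agents = 4L, n_small = 4L, n_large = 0L,
                     sigma_small = 0.1, sigma_large = 1,
                     n_iterations = 1L, measure_every = 1L)
  expect_error(group_mean(1:4, group_assignment(p0), "L"), "empty")

  expect_equal(variation_coefficient(c(0.3, 0.3, 0.3)), 0)
  # population SD of (-0.2, -0.4) is 0.1, |mean| is 0.3
  expect_equal(variation_coefficient(c(-0.2, -0.4)), 1 / 3)
  x <- c(-0.1, -0.5, -0.3)
  expect_equal(variation_coefficient(7 * x), variation_coefficient(x))
  expect_error(variation_coefficient(c(-1, 1)), "zero mean")
})

test_that("consensual stratification is the group's reputation spread", {
  p <- tiny_params(4L)
  g <- group_assignment(p)
  cmat <- matrix(0.25, 4, 4)
  expect_equal(consensual_stratification(cmat, g, "S"), 0)
  # build a matrix whose S-group reputations are 0.1 and 0.3
  a <- matrix(0, 4, 4)
  a[-1, 1] <- 0.1
  a[-2, 2] <- 0.3
  expect_equal(consensual_stratification(a, g, "S"), 0.1)
  # perturbing only L-group columns leaves the S statistic unchanged
  b <- a
  b[-3, 3] <- b[-3, 3] + 0.5
  expect_equal(consensual_stratification(b, g, "S"),
               consensual_stratification(a, g, "S"))
})

test_that("ranks sort reputations descending with index tie-break", {
  # reputations (0.2, -0.1, 0.5) -> ranks (2, 3, 1)
  a <- matrix(0, 3, 3)
  a[-1, 1] <- 0.2
  a[-2, 2] <- -0.1
  a[-3, 3] <- 0.5
  expect_equal(rank_vector(a), c(2L, 3L, 1L))
  expect_equal(rank_vector(matrix(0.4, 5, 5)), 1:5)
  set.seed(8)
  for (rep in 1:5) {
    m <- matrix(runif(36, -1, 1), 6, 6)
    expect_setequal(rank_vector(m), 1:6)
  }
})

test_that("occupancy probabilities are complementary and sum to one", {
  labels <- c("S", "S", "L", "L")
  recs <- make_records(list(c(1L, 2L, 3L, 4L), c(2L, 1L, 4L, 3L),
                            c(1L, 3L, 2L, 4L)), labels)
  occ <- occupancy_probability(recs)
  wide <- data.table::dcast(occ, rank ~ group, value.var = "probability",
                            fill = 0)
  expect_equal(wide$S + wide$L, rep(1, 4))
  expect_equal(occ[occ$group == "L" & occ$rank == 4, ]$probability, 1)
  expect_equal(occ[occ$group == "L" & occ$rank == 2, ]$probability, 1 / 3)
})

test_that("glass ceiling is the best pooled L rank and shrinks with data", {
  labels <- c("S", "S", "L", "L")
  r1 <- make_records(list(c(1L, 2L, 3L, 4L)), labels)
  expect_equal(glass_ceiling_rank(r1), 3L)
  r2 <- make_records(list(c(1L, 2L, 3L, 4L), c(2L, 3L, 1L, 4L)), labels)
  expect_equal(glass_ceiling_rank(r2), 1L)
  # pooling more observations can only improve (lower) the minimum
  expect_lte(glass_ceiling_rank(r2), glass_ceiling_rank(r1))
  only_s <- make_records(list(c(1L, 2L)), c("S", "S"))
  expect_error(glass_ceiling_rank(only_s), "no L")
})

test_that("advancement counts non-worsening transitions per group and rank", {
  labels <- c("S", "L")
  # agent 1: ranks 1 -> 1 -> 2; agent 2: ranks 2 -> 2 -> 1
  recs <- make_records(list(c(1L, 2L), c(1L, 2L), c(2L, 1L)), labels)
  adv <- advancement_probability(recs)
  expect_equal(adv[adv$group == "S" & adv$rank == 1, ]$probability, 0.5)
  expect_equal(adv[adv$group == "L" & adv$rank == 2, ]$probability, 1)
  expect_equal(adv[adv$group == "L" & adv$rank == 2, ]$n_obs, 2L)
  # a 5 -> 3 move is a success for (group, rank 5)
  labels6 <- c("S", "S", "S", "L", "L", "L")
  recs6 <- make_records(list(c(1L, 2L, 4L, 3L, 5L, 6L),
                             c(1L, 2L, 5L, 3L, 4L, 6L)), labels6)
  adv6 <- advancement_probability(recs6)
  expect_equal(adv6[adv6$group == "L" & adv6$rank == 5, ]$probability, 1)
  expect_error(advancement_probability(make_records(list(c(1L, 2L)), labels)),
               "2 snapshots")
})

test_that("frozen noiseless dynamics give advancement probability one", {
  params <- quiet_params(6L, n_agents = 6L, n_iterations = 40L,
                         measure_every = 10L)
  s <- run_simulation(params)
  recs <- rank_records(s, stationary = FALSE)
  adv <- advancement_probability(recs)
  expect_true(all(adv$probability == 1))
})

test_that("extreme-rank Z-score implements the binomial standardisation", {
  labels <- c("S", "S", "L", "L")  # q = 0.5
  # 10 snapshots, n_extreme = 1: rank 1 always S -> X = 0
  recs <- make_records(rep(list(c(1L, 2L, 3L, 4L)), 10), labels)
  z_top <- extreme_rank_zscore(recs, n_extreme = 1L, side = "top")
  expect_equal(z_top, (0 - 10 * 0.5) / sqrt(10 * 0.25))
  z_bot <- extreme_rank_zscore(recs, n_extreme = 1L, side = "bottom")
  expect_equal(z_bot, (10 - 10 * 0.5) / sqrt(10 * 0.25))
  # balanced occupancy gives Z = 0
  bal <- make_records(list(c(1L, 2L, 3L, 4L), c(3L, 4L, 1L, 2L)), labels)
  expect_equal(extreme_rank_zscore(bal, n_extreme = 1L, side = "top"), 0)
  expect_error(extreme_rank_zscore(make_records(list(c(1L, 2L)), c("L", "L"))),
               "fraction")
})

test_that("group summaries report the documented columns and values", {
  params <- quiet_params(4L, n_agents = 4L, n_iterations = 0L)
  s <- run_simulation(params)
  gs <- group_summary(s)
  expect_named(gs, c("replica", "t", "group", "mean_reputation",
                     "mean_self_esteem", "cv_self_esteem", "cv_reputation",
                     "sd_reputation"))
  expect_equal(nrow(gs), 2L)
  expect_equal(gs$mean_reputation, c(0, 0))
  expect_true(all(is.na(gs$cv_self_esteem)))  # zero means at the start
})
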
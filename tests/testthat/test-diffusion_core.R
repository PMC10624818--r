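week_table <- function(weeks, ids = sprintf("n%02d", seq_along(weeks))) {
  data.frame(unit_id = ids, duration_weeks = weeks,
             week = week_from_duration(weeks), censored = FALSE)
}

test_that("empirical state encoding steps at the discretized week", {
  tbl <- week_table(c(2, 14))
  S <- states_from_durations(tbl, tbl$unit_id)
  expect_equal(unname(S["n01", ]), c(0L, 0L, rep(1L, 13L)))
  expect_equal(unname(S["n02", ]), c(rep(0L, 14L), 1L))
  tbl3 <- week_table(c(1.14, 3.0, 14.2))
  expect_equal(tbl3$week, c(2L, 3L, 14L))
  S3 <- states_from_durations(tbl3, tbl3$unit_id)
  expect_equal(unname(colSums(S3)), c(0, 0, 1, rep(2, 11), 3))
  expect_error(states_from_durations(tbl, c("n01", "zz")), "zz")
})

test_that("simulate honours zero and unreachable thresholds", {
  g <- build_contiguity_graph(
    generate_units(synthetic_scenario(rows = 3, cols = 3)), "queen")
  S0 <- simulate_diffusion(g, rep(0, 9))
  expect_equal(unname(colSums(S0)), c(0, 0, rep(9, 13)))
  S1 <- simulate_diffusion(g, rep(1, 9))
  expect_equal(sum(S1), 0)
})

test_that("simulate follows the update rule on a hand-simulated path", {
  g <- graph_from_edgelist(rbind(c("a", "b"), c("b", "c")))
  S <- simulate_diffusion(g, c(0, 0.5, 0.5))
  first_week <- apply(S, 1L, function(x) which(x == 1L)[1L] - 1L)
  expect_equal(unname(first_week), c(2L, 3L, 4L))
})

test_that("isolates recover only at threshold zero", {
  g <- graph_from_edgelist(rbind(c("a", "b")), vertices = c("a", "b", "iso"))
  S <- simulate_diffusion(g, c(1, 1, 0))
  expect_equal(unname(S["iso", ]), c(0L, 0L, rep(1L, 13L)))
  S2 <- simulate_diffusion(g, c(1, 1, 0.01))
  expect_equal(sum(S2["iso", ]), 0L)
})

test_that("0-1 loss counts disagreeing cells over t = 1..T", {
  tbl <- week_table(c(2, 3, 5))
  S <- states_from_durations(tbl, tbl$unit_id)
  expect_equal(recovery_loss(S, S), 0L)
  Shat <- states_from_durations(week_table(c(2, 4, 4)), tbl$unit_id)
  expect_equal(recovery_loss(S, Shat), 2L)
  expect_equal(recovery_loss(Shat, S), 2L)
  n <- 5L
  none <- matrix(0L, n, 15L)
  all1 <- cbind(rep(0L, n), matrix(1L, n, 14L))
  expect_equal(recovery_loss(none, all1), n * 14L)
  expect_error(recovery_loss(none, all1[, 1:10]), "mismatch")
})

test_that("weekly curves tally cumulative recoveries and differences", {
  tbl <- week_table(c(2, 2, 3, 14))
  S <- states_from_durations(tbl, tbl$unit_id)
  counts <- weekly_recovery_counts(S)
  expect_equal(unname(counts[c("t2", "t3", "t14")]), c(2, 3, 4))
  d <- weekly_recovery_difference(S, S)
  expect_true(all(d$new_diff == 0) && all(d$accumulated_diff == 0))
  Shat <- states_from_durations(week_table(c(2, 3, 3, 14)), tbl$unit_id)
  d2 <- weekly_recovery_difference(S, Shat)
  expect_equal(d2$accumulated_diff, unname(colSums(S) - colSums(Shat)))
  expect_equal(cumsum(d2$new_diff), d2$accumulated_diff)
})

test_that("simulate agrees with the from-scratch oracle on random graphs", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    g <- random_graph(n)
    tau <- runif(n)
    ns <- sample(0:n, 1)
    seeds <- if (ns > 0) sample(g$vertices, ns) else character(0)
    T <- sample(2:5, 1)
    cfg <- diffusion_config(T = T)
    S <- simulate_diffusion(g, tau, seeds, cfg)
    O <- oracle_simulate(g$adj, tau, match(seeds, g$vertices), T)
    expect_equal(matrix(as.integer(S), nrow(S), ncol(S)), O)
  }
})

test_that("states are absorbing and monotone in the seed set", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    g <- random_graph(n, p = 0.35)
    tau <- runif(n)
    A <- sample(g$vertices, 2)
    B <- union(A, sample(g$vertices, 2))
    SA <- simulate_diffusion(g, tau, A)
    SB <- simulate_diffusion(g, tau, B)
    expect_true(all(apply(SA, 1L, function(x) all(diff(x) >= 0))))
    finalA <- g$vertices[SA[, ncol(SA)] == 1L]
    finalB <- g$vertices[SB[, ncol(SB)] == 1L]
    expect_true(all(finalA %in% finalB))
  }
})

test_that("randomized baseline is deterministic given a seed and mask", {
  d <- grid_fixture(4, 4, seed = 5L)
  b1 <- randomized_baseline(d$g, d$emp, d$gt$zero_mask, n_runs = 20,
                            seed = 123)
  b2 <- randomized_baseline(d$g, d$emp, d$gt$zero_mask, n_runs = 20,
                            seed = 123)
  expect_identical(b1$losses, b2$losses)
  expect_equal(b1$mean_loss, mean(b1$losses))

  # all units masked: every run is the deterministic all-zero simulation
  full_mask <- rep(TRUE, length(d$g$vertices))
  b3 <- randomized_baseline(d$g, d$emp, full_mask, n_runs = 5, seed = 1)
  ref <- recovery_loss(d$emp,
                       simulate_diffusion(d$g, rep(0, length(full_mask))))
  expect_true(all(b3$losses == ref))
})
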
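test_that("calibration recovers a planted model on a small lattice", {
  d <- grid_fixture(4, 4, zero_seed_fraction = 0.5, seed = 2L)
  cal <- calibrate_thresholds(d$g, d$emp, d$gt$zero_mask,
                              ga_config(max_generations = 3000, seed = 1))
  expect_equal(cal$final_loss, 0L)
  expect_identical(matrix(as.integer(cal$simulated), 16, 15),
                   matrix(as.integer(d$emp), 16, 15))
  # every recovered free threshold sits in its identifiable interval
  for (i in which(!d$gt$zero_mask)) {
    iv <- identifiable_interval(d$emp, d$g$adj, i)
    tau_i <- cal$tau_star$values[i]
    expect_gt(tau_i, iv["lo"])
    expect_lte(tau_i, iv["hi"])
  }
  expect_true(all(cal$tau_star$values[d$gt$zero_mask] == 0))
})

test_that("an all-masked calibration needs no search", {
  tbl <- data.frame(unit_id = c("a", "b"), duration_weeks = c(1.5, 1.8),
                    week = c(2L, 2L), censored = FALSE)
  g <- graph_from_edgelist(rbind(c("a", "b")))
  emp <- states_from_durations(tbl, g$vertices)
  cal <- calibrate_thresholds(g, emp, c(TRUE, TRUE))
  expect_equal(cal$final_loss, 0L)
  expect_equal(cal$tau_star$values, c(0, 0))
  expect_equal(cal$ga$generations, 0L)
})

test_that("a single free threshold is identified up to its interval", {
  # 3x3 queen lattice, all masked except the center; the center's
  # attainable neighbor fractions jump 0 -> 1 at week 2, so any positive
  # threshold reproduces recovery at week 3 and zero gives week 2
  units <- generate_units(synthetic_scenario(rows = 3, cols = 3))
  g <- build_contiguity_graph(units, "queen")
  mask <- rep(TRUE, 9); mask[5] <- FALSE
  tau_true <- rep(0, 9); tau_true[5] <- 0.62
  emp <- simulate_diffusion(g, tau_true)
  center_week <- unname(which(emp[5, ] == 1L)[1L] - 1L)
  expect_equal(center_week, 3L)
  # brute-force scan: which constant thresholds reproduce the trajectory?
  grid <- seq(0, 1, by = 0.001)
  repro <- vapply(grid, function(v) {
    tau <- tau_true; tau[5] <- v
    recovery_loss(emp, simulate_diffusion(g, tau)) == 0L
  }, TRUE)
  iv <- identifiable_interval(emp, g$adj, 5L)
  expect_equal(range(grid[repro]), c(0.001, 1))
  expect_equal(unname(iv), c(0, 1))
  tbl <- data.frame(unit_id = g$vertices,
                    duration_weeks = ifelse(mask, 1.5, 2.5),
                    week = ifelse(mask, 2L, 3L), censored = FALSE)
  cal <- calibrate_thresholds(g, states_from_durations(tbl, g$vertices),
                              mask, ga_config(max_generations = 200, seed = 3))
  expect_equal(cal$final_loss, 0L)
  expect_gt(cal$tau_star$values[5], 0)
})

test_that("multiplier optimization matches exhaustive enumeration", {
  # 10-node path with uniform thresholds 0.6: brute force over singletons
  ids <- sprintf("p%02d", 1:10)
  g <- graph_from_edgelist(cbind(ids[-10], ids[-1]), vertices = ids)
  tau <- threshold_vector(rep(0.6, 10))
  exhaustive <- function(N) {
    combos <- utils::combn(ids, N, simplify = FALSE)
    max(vapply(combos, function(s) {
      S <- simulate_diffusion(g, tau, seeds = s)
      sum(S[, ncol(S)])
    }, 0))
  }
  ms1 <- optimize_multipliers(g, tau, 1L,
                              ga_config(max_generations = 150, seed = 5,
                                        stop_at_loss = NULL))
  expect_equal(ms1$recovered_at_T, exhaustive(1L))

  # 4x4 queen lattice, heterogeneous thresholds, pairs: C(16,2) = 120
  d <- grid_fixture(4, 4, zero_seed_fraction = 0.25, seed = 8L)
  tau2 <- d$gt$tau
  combos <- utils::combn(d$g$vertices, 2L, simplify = FALSE)
  best <- max(vapply(combos, function(s) {
    S <- simulate_diffusion(d$g, tau2, seeds = s)
    sum(S[, ncol(S)])
  }, 0))
  ms2 <- optimize_multipliers(d$g, tau2, 2L,
                              ga_config(max_generations = 400, seed = 5,
                                        stop_at_loss = NULL))
  expect_equal(ms2$recovered_at_T, best)
})

test_that("edge seed-set sizes behave trivially and respect monotonicity", {
  d <- grid_fixture(4, 4, seed = 13L)
  n <- length(d$g$vertices)
  all_in <- optimize_multipliers(d$g, d$gt$tau, n,
                                 ga_config(max_generations = 5, seed = 1,
                                           stop_at_loss = NULL))
  expect_equal(all_in$recovered_at_T, n)
  none <- optimize_multipliers(d$g, d$gt$tau, 0L)
  unseeded <- simulate_diffusion(d$g, d$gt$tau)
  expect_equal(none$recovered_at_T, sum(unseeded[, ncol(unseeded)]))
  some <- optimize_multipliers(d$g, d$gt$tau, 3L,
                               ga_config(max_generations = 50, seed = 2,
                                         stop_at_loss = NULL))
  expect_gte(some$recovered_at_T, none$recovered_at_T)
  expect_gte(some$recovered_at_T, some$baseline_recovered)
  expect_error(optimize_multipliers(d$g, d$gt$tau, n + 1L), "exceeds")
})

test_that("increment rate reproduces the printed seed-set gains", {
  expect_equal(increment_rate(1627, 1724), 5.96)
  expect_equal(increment_rate(1676, 1932), 15.27)
  expect_equal(increment_rate(1741, 1998), 14.76)
  expect_equal(increment_rate(500, 500), 0)
  expect_error(increment_rate(0, 10), "positive")
})

test_that("affected-at-horizon is the complement of the final recovered count", {
  S <- cbind(matrix(0L, 5, 1), matrix(1L, 5, 14))
  expect_equal(affected_at_horizon(S), 0L)
  expect_equal(affected_at_horizon(matrix(0L, 5, 15)), 5L)
  S2 <- states_from_durations(
    data.frame(unit_id = c("a", "b", "c"), duration_weeks = c(2, 3, 14),
               week = c(2L, 3L, 14L), censored = c(FALSE, FALSE, TRUE)),
    c("a", "b", "c"))
  expect_equal(affected_at_horizon(S2), 0L)
  expect_equal(affected_at_horizon(S2[, 1:14]), 1L)
})
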
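# Shared fixtures: small planted scenarios, an independent brute-force
# diffusion oracle, and the threshold-identifiability interval helper.

grid_fixture <- function(rows, cols, zero_seed_fraction = 0.37, seed = 1L,
                         ...) {
  scen <- synthetic_scenario(rows = rows, cols = cols,
                             zero_seed_fraction = zero_seed_fraction,
                             seed = seed, ...)
  units <- generate_units(scen)
  g <- build_contiguity_graph(units, "queen")
  gt <- generate_ground_truth(scen, g)
  list(scenario = scen, units = units, g = g, gt = gt,
       emp = states_from_durations(gt$table, g$vertices))
}

# Independent oracle: re-evaluates the recovered-neighbor-fraction rule
# from scratch each week, in plain R, against the previous week's states.
oracle_simulate <- function(nbr, tau, seed_idx, T, first_update_week = 2L) {
  n <- length(tau)
  S <- matrix(0L, n, T + 1L)
  if (length(seed_idx) > 0L) S[seed_idx, 1L] <- 1L
  for (t in seq_len(T)) {
    prev <- S[, t]
    cur <- prev
    if (t >= first_update_week) {
      for (i in seq_len(n)) {
        if (prev[i] == 1L) next
        d <- length(nbr[[i]])
        f <- if (d == 0L) 0 else sum(prev[nbr[[i]]]) / d
        if (f >= tau[i]) cur[i] <- 1L
      }
    }
    S[, t + 1L] <- cur
  }
  S
}

random_graph <- function(n, p = 0.4) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  ids <- sprintf("v%02d", seq_len(n))
  graph_from_edgelist(cbind(ids[pairs[keep, 1L]], ids[pairs[keep, 2L]]),
                      vertices = ids)
}

# Identifiable threshold interval (lo, hi] for unit i given an empirical
# trajectory it must reproduce: hi is the recovered-neighbor fraction the
# week before recovery, lo the fraction one week earlier (-Inf at the
# first update week, where any sufficiently small threshold works).
identifiable_interval <- function(emp, adj, i, first_update_week = 2L) {
  w <- which(emp[i, ] == 1L)[1L] - 1L
  d <- length(adj[[i]])
  f <- function(t) if (d == 0L) 0 else mean(emp[adj[[i]], t + 1L])
  hi <- f(w - 1L)
  lo <- if (w > first_update_week) f(w - 2L) else -Inf
  c(lo = lo, hi = hi)
}

# Edge list with the empirical study's printed graph size: a 2010-vertex
# circulant-style construction with exactly 6079 distinct edges.
study_size_graph <- function() {
  n <- 2010L
  ids <- sprintf("c%04d", seq_len(n))
  nxt <- function(k, take = n) {
    i <- seq_len(take)
    cbind(ids[i], ids[(i + k - 1L) %% n + 1L])
  }
  edges <- rbind(nxt(1L), nxt(2L), nxt(3L), nxt(4L, take = 49L))
  graph_from_edgelist(edges, vertices = ids)
}
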
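#' Diffusion configuration
#'
#' The horizon is 14 weeks; all units are affected at `t = 0` and, by
#' convention, states are held through week 1 so that the first group of
#' zero-threshold units recovers at the end of week 2 (`first_update_week =
#' 2`). The neighbor-fraction comparison is `>=` (ties recover) and isolates
#' have neighbor fraction 0, so an isolate recovers iff its threshold is 0.
#'
#' @param T Horizon in weeks (default 14).
#' @param first_update_week First week at which the update rule is applied.
#' @return A list of class `diffusion_config`.
#' @export
diffusion_config <- function(T = 14L, first_update_week = 2L) {
  T <- as.integer(T); first_update_week <- as.integer(first_update_week)
  stopifnot(first_update_week >= 1L, first_update_week <= T)
  structure(list(T = T, first_update_week = first_update_week),
            class = "diffusion_config")
}

#' Per-unit threshold vector
#'
#' Thresholds in `[0,1]` aligned to a graph's vertex order, with an optional
#' mask of units constrained to threshold zero (the first group to recover).
#' Masked entries are clamped to zero.
#'
#' @param values Numeric vector in `[0,1]`.
#' @param fixed_zero_mask Logical vector (same length) of units fixed at 0,
#'   or `NULL` for none.
#' @return An object of class `threshold_vector`.
#' @export
threshold_vector <- function(values, fixed_zero_mask = NULL) {
  values <- as.numeric(values)
  if (any(values < 0 | values > 1)) stop("thresholds must lie in [0,1]")
  if (is.null(fixed_zero_mask)) fixed_zero_mask <- rep(FALSE, length(values))
  stopifnot(length(fixed_zero_mask) == length(values))
  values[fixed_zero_mask] <- 0
  structure(list(values = values, fixed_zero_mask = fixed_zero_mask),
            class = "threshold_vector")
}

#' @export
print.threshold_vector <- function(x, ...) {
  cat("<threshold_vector: n = ", length(x$values), ", ",
      sum(x$fixed_zero_mask), " fixed at zero>\n", sep = "")
  invisible(x)
}

as_tau_values <- function(tau, n) {
  v <- if (inherits(tau, "threshold_vector")) tau$values else as.numeric(tau)
  if (length(v) != n) stop("threshold vector not aligned to graph (length ",
                           length(v), " vs ", n, ")")
  v
}

# Flattened 0-based adjacency for the C++ kernel.
flat_adj <- function(g) {
  ptr <- c(0L, cumsum(g$degree))
  list(flat = as.integer(unlist(g$adj, use.names = FALSE) - 1L),
       ptr = as.integer(ptr))
}

new_trajectory <- function(mat, vertices, role = "simulated") {
  dimnames(mat) <- list(vertices, paste0("t", seq_len(ncol(mat)) - 1L))
  attr(mat, "role") <- role
  mat
}

#' Encode empirical weekly states from recovery durations
#'
#' Produces the binary unit-by-week state matrix `S` with `S[i, t] = 1` iff
#' the unit's discretized recovery week is `<= t`. All units are affected at
#' `t = 0`. Right-censored durations are designated week 14, so censored
#' units flip to recovered at the horizon.
#'
#' @param table Recovery table with `unit_id` and `week` columns.
#' @param vertex_order Character vector giving the row order (the graph's
#'   vertices); every vertex must have a row.
#' @param T Horizon in weeks.
#' @return Integer matrix `n x (T+1)` with columns `t0..tT`.
#' @export
states_from_durations <- function(table, vertex_order, T = 14L) {
  i <- match(vertex_order, table$unit_id)
  if (anyNA(i))
    stop("missing duration row for unit '", vertex_order[is.na(i)][1L], "'")
  week <- table$week[i]
  S <- outer(week, 0:T, function(w, t) as.integer(w <= t))
  new_trajectory(S, vertex_order, role = "empirical")
}

#' Simulate the threshold diffusion process
#'
#' Synchronous deterministic dynamics: seeds are recovered from `t = 0`; for
#' each week `t` from `first_update_week` to `T`, a unit becomes recovered
#' if the fraction of its neighbors recovered at `t - 1` is at least its
#' threshold. Recovery is absorbing. Zero-threshold units always satisfy
#' the rule and recover at `first_update_week` if not seeded earlier.
#'
#' @param g A `contiguity_graph`.
#' @param tau A [threshold_vector()] (or numeric vector) aligned to `g`.
#' @param seeds Character vector of unit ids recovered at `t = 0`.
#' @param cfg A [diffusion_config()].
#' @return Integer state matrix `n x (T+1)` with unit-id rownames.
#' @export
simulate_diffusion <- function(g, tau, seeds = character(0),
                               cfg = diffusion_config()) {
  stopifnot(inherits(g, "contiguity_graph"))
  n <- length(g$vertices)
  v <- as_tau_values(tau, n)
  sidx <- match(seeds, g$vertices)
  if (anyNA(sidx)) stop("seed not in graph: ", seeds[is.na(sidx)][1L])
  fa <- flat_adj(g)
  S <- sim_trajectory_cpp(fa$flat, fa$ptr, v, as.integer(sidx - 1L),
                          cfg$T, cfg$first_update_week)
  new_trajectory(S, g$vertices)
}

#' 0-1 loss between two state trajectories
#'
#' Counts the unit-week cells where the trajectories disagree, summed over
#' `t = 1..T` (the fixed all-affected column `t = 0` is excluded).
#'
#' @param S,S_hat State matrices of identical shape.
#' @return Non-negative integer count.
#' @export
recovery_loss <- function(S, S_hat) {
  if (!all(dim(S) == dim(S_hat))) stop("trajectory shape mismatch")
  sum(S[, -1L, drop = FALSE] != S_hat[, -1L, drop = FALSE])
}

#' Cumulative recovered counts per week
#'
#' @param S A state trajectory.
#' @return Named integer vector of recovered counts at `t = 0..T`.
#' @export
weekly_recovery_counts <- function(S) {
  colSums(S)
}

#' Weekly difference between two recovery curves
#'
#' Compares the per-week newly recovered counts of two trajectories
#' (typically empirical vs simulated) and accumulates the difference; the
#' accumulated series equals the difference of the cumulative curves. When
#' durations are right-censored at the horizon, the horizon-week difference
#' is inflated by the censoring designation rather than by model error.
#'
#' @param S,S_hat State trajectories of identical shape.
#' @return Data frame with `t`, `count`, `count_hat`, `new_diff`,
#'   `accumulated_diff`.
#' @export
weekly_recovery_difference <- function(S, S_hat) {
  if (!all(dim(S) == dim(S_hat))) stop("trajectory shape mismatch")
  a <- colSums(S); b <- colSums(S_hat)
  data.frame(t = seq_along(a) - 1L,
             count = a, count_hat = b,
             new_diff = c(a[1L] - b[1L], diff(a) - diff(b)),
             accumulated_diff = a - b,
             row.names = NULL)
}

#' Randomized-threshold baseline loss
#'
#' Draws free thresholds uniformly on `[0,1]` (masked units stay at zero),
#' simulates the diffusion, and records the loss against the empirical
#' trajectory; repeated `n_runs` times. The mean loss serves as the
#' no-optimization baseline for the calibration stage.
#'
#' @param g A `contiguity_graph`.
#' @param empirical Empirical state trajectory aligned to `g`.
#' @param mask Logical fixed-zero mask aligned to `g` (or `NULL`).
#' @param n_runs Number of randomized runs (study default 1000).
#' @param cfg A [diffusion_config()].
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `losses` (length `n_runs`) and `mean_loss`.
#' @export
randomized_baseline <- function(g, empirical, mask = NULL, n_runs = 1000L,
                                cfg = diffusion_config(), seed = NULL) {
  stopifnot(n_runs >= 1L)
  n <- length(g$vertices)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (!is.null(seed)) set.seed(seed)
  fa <- flat_adj(g)
  emp <- matrix(as.integer(empirical), nrow(empirical), ncol(empirical))
  losses <- vapply(seq_len(n_runs), function(r) {
    v <- stats::runif(n)
    v[mask] <- 0
    sim_loss_cpp(fa$flat, fa$ptr, v, integer(0), cfg$T,
                 cfg$first_update_week, emp)
  }, 0L)
  list(losses = losses, mean_loss = mean(losses))
}

#' Write a state trajectory as wide CSV
#'
#' @param S State trajectory.
#' @param path Output path (`unit_id,t0..tT`).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(S, path) {
  df <- data.frame(unit_id = rownames(S), as.data.frame(unclass(S)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
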
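# Deterministic seed derivation: one global seed, one stream per stage.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 1009 * h) %% 2147483629)
}

#' Synthetic study scenario
#'
#' Defines the conditions under which every pipeline input is generated
#' with known ground truth: a lattice of unit-square polygons (optionally
#' vertex-jittered while keeping adjacency), a planted share of
#' zero-threshold units that recover first, free thresholds drawn from a
#' chosen distribution, observation noise on the recorded recovery week,
#' and a planted sociodemographic gap between early- and late-recovering
#' units. The defaults emulate the empirical setting at desk scale: a
#' 10 x 10 grid (interior queen degree 8), 37% zero-threshold units
#' (mirroring 750 of 2010), uniform free thresholds and noiseless
#' observation.
#'
#' @param rows,cols Lattice dimensions (`rows*cols >= 4`).
#' @param layout `"grid"` or `"perturbed-grid"` (jittered shared vertices).
#' @param jitter Vertex jitter amplitude as a fraction of the cell size
#'   (perturbed layout only; must stay below 0.5 to keep cells valid).
#' @param zero_seed_fraction Share of units planted with threshold zero.
#' @param tau_distribution `"uniform"` or `"beta"` for free thresholds.
#' @param beta_shape1,beta_shape2 Beta parameters when
#'   `tau_distribution = "beta"`.
#' @param noise Per-unit probability that the observed recovery week is
#'   perturbed by one week (clamped to `{2..14}`).
#' @param ensure_saturation When `TRUE` (default), thresholds of units the
#'   forward cascade never reaches are lowered until every unit recovers
#'   within the horizon, so planted data contain no right-censoring and
#'   noiseless round trips are exact. Set `FALSE` to study censoring.
#' @param demographic_model Named list of base levels, planted gaps and
#'   noise standard deviations for the demographic generator.
#' @param seed RNG seed; all generators derive their streams from it.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(rows = 10L, cols = 10L,
                               layout = c("grid", "perturbed-grid"),
                               jitter = 0.15,
                               zero_seed_fraction = 0.37,
                               tau_distribution = c("uniform", "beta"),
                               beta_shape1 = 2, beta_shape2 = 2,
                               noise = 0,
                               ensure_saturation = TRUE,
                               demographic_model = list(
                                 income_base = 60000, income_gap = 15000,
                                 pci_base = 32000, pci_gap = 8000,
                                 minority_base = 30, minority_gap = 20,
                                 income_sd = 3000, pci_sd = 1500,
                                 minority_sd = 5),
                               seed = NULL) {
  layout <- match.arg(layout)
  tau_distribution <- match.arg(tau_distribution)
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows * cols >= 4L,
            zero_seed_fraction >= 0, zero_seed_fraction <= 1,
            noise >= 0, noise <= 1, jitter >= 0, jitter < 0.5)
  structure(list(rows = rows, cols = cols, layout = layout, jitter = jitter,
                 zero_seed_fraction = zero_seed_fraction,
                 tau_distribution = tau_distribution,
                 beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
                 noise = noise, ensure_saturation = ensure_saturation,
                 demographic_model = demographic_model, seed = seed),
            class = "synthetic_scenario")
}

#' Generate lattice spatial units
#'
#' `rows x cols` unit-square cells on a shared vertex lattice; in the
#' perturbed layout interior lattice vertices are jittered, which deforms
#' cells without changing which cells touch (shared vertices stay shared).
#'
#' @param scenario A [synthetic_scenario()].
#' @return List of [spatial_unit()] objects in row-major order, with ids
#'   `u0001, u0002, ...`.
#' @export
generate_units <- function(scenario) {
  s <- derive_seed(scenario$seed, "units")
  if (!is.null(s)) set.seed(s)
  R <- scenario$rows; C <- scenario$cols
  vx <- outer(0:R, 0:C, function(r, c) c * 1.0)
  vy <- outer(0:R, 0:C, function(r, c) r * 1.0)
  if (scenario$layout == "perturbed-grid" && scenario$jitter > 0) {
    ir <- 2:R; ic <- 2:C  # interior lattice vertices only
    vx[ir, ic] <- vx[ir, ic] +
      stats::runif(length(ir) * length(ic), -scenario$jitter, scenario$jitter)
    vy[ir, ic] <- vy[ir, ic] +
      stats::runif(length(ir) * length(ic), -scenario$jitter, scenario$jitter)
  }
  units <- vector("list", R * C)
  k <- 0L
  for (r in seq_len(R)) for (c in seq_len(C)) {
    k <- k + 1L
    ring <- rbind(c(vx[r, c],         vy[r, c]),
                  c(vx[r, c + 1L],     vy[r, c + 1L]),
                  c(vx[r + 1L, c + 1L], vy[r + 1L, c + 1L]),
                  c(vx[r + 1L, c],     vy[r + 1L, c]))
    units[[k]] <- spatial_unit(sprintf("u%04d", k), ring)
  }
  units
}

#' Generate planted ground truth: thresholds, trajectory, durations
#'
#' Samples the fixed-zero mask and free thresholds, forward-simulates the
#' threshold diffusion to the horizon, and derives continuous recovery
#' durations consistent with the simulated weeks: each unit recovering in
#' week `w` is assigned a recovery day uniformly among the seven days of
#' that week, giving `duration = w - 1 + (j+1)/7` for day offset
#' `j in 0..6` (minimum `8/7 = 1.14` weeks). With `ensure_saturation`
#' (default) thresholds of unreached units are lowered to their final
#' recovered-neighbor fraction, iterating until the cascade saturates, so
#' no unit is right-censored; otherwise unreached units are censored at 14
#' weeks. Observation noise flips each recorded week by one with the
#' scenario's noise probability.
#'
#' @param scenario A [synthetic_scenario()].
#' @param g The contiguity graph built from [generate_units()].
#' @param dcfg A [diffusion_config()].
#' @return List with `tau` ([threshold_vector()]), `trajectory` (simulated
#'   states), `table` (recovery table data frame), `zero_mask`, and
#'   `summary` (n, m, average degree, zero-seed count, week histogram).
#' @export
generate_ground_truth <- function(scenario, g, dcfg = diffusion_config()) {
  s <- derive_seed(scenario$seed, "ground_truth")
  if (!is.null(s)) set.seed(s)
  n <- length(g$vertices)
  n_zero <- round(scenario$zero_seed_fraction * n)
  mask <- rep(FALSE, n)
  if (n_zero > 0L) mask[sample.int(n, n_zero)] <- TRUE
  v <- if (scenario$tau_distribution == "beta")
    stats::rbeta(n, scenario$beta_shape1, scenario$beta_shape2)
  else stats::runif(n)
  v[mask] <- 0
  fa <- flat_adj(g)
  sim <- function(tau) sim_trajectory_cpp(fa$flat, fa$ptr, tau, integer(0),
                                          dcfg$T, dcfg$first_update_week)
  S <- sim(v)
  if (scenario$ensure_saturation) {
    repeat {
      final <- S[, ncol(S)]
      if (all(final == 1L)) break
      stuck <- which(final == 0L)
      frac <- vapply(stuck, function(i) {
        nb <- g$adj[[i]]
        if (length(nb) == 0L) 0 else mean(final[nb])
      }, 0)
      v[stuck] <- frac  # recovers units with recovered neighbors; isolates -> 0
      S <- sim(v)
    }
  }
  final <- S[, ncol(S)]
  week <- rep(NA_integer_, n)
  rec <- which(final == 1L)
  week[rec] <- apply(S[rec, , drop = FALSE], 1L, function(x) which(x == 1L)[1L]) - 1L
  censored <- is.na(week)
  j <- sample.int(7L, n, replace = TRUE) - 1L
  duration <- ifelse(censored, 14, week - 1 + (j + 1) / 7)
  obs_week <- ifelse(censored, 14L, week)
  if (scenario$noise > 0) {
    flip <- stats::runif(n) < scenario$noise & !censored
    dir <- sample(c(-1L, 1L), n, replace = TRUE)
    neww <- pmin(pmax(obs_week + dir, 2L), 14L)
    j2 <- sample.int(7L, n, replace = TRUE) - 1L
    obs_week[flip] <- neww[flip]
    duration[flip] <- neww[flip] - 1 + (j2[flip] + 1) / 7
  }
  table <- data.frame(unit_id = g$vertices,
                      duration_weeks = duration,
                      week = as.integer(obs_week),
                      censored = censored,
                      stringsAsFactors = FALSE)
  st <- graph_stats(g)
  summary <- list(n = st$n, m = st$m, avg_degree = st$avg_degree,
                  zero_seed_count = sum(mask),
                  week_histogram = table(factor(table$week, levels = 2:14)))
  S <- new_trajectory(S, g$vertices)
  list(tau = threshold_vector(v, mask), trajectory = S, table = table,
       zero_mask = mask, summary = summary)
}

#' Generate daily visit series that invert to planted durations
#'
#' Each unit's raw series sits exactly at its baseline level through the
#' baseline window, drops to `post_drop_fraction` of baseline after it, and
#' steps back to baseline two days before the planted recovery day — the
#' offset at which the centred 7-day moving average of a half-level step
#' first reaches 90% of baseline — so the preprocessing chain recovers the
#' planted recovery day, and hence week, exactly. Censored units never
#' return to baseline in-window. Optional Poisson observation noise
#' replaces each count with a Poisson draw at that mean (breaking
#' exactness).
#'
#' @param table Recovery table (from [generate_ground_truth()]).
#' @param baseline_level Baseline mean daily visits (recycled over units).
#' @param config A [preprocess_config()] fixing the calendar.
#' @param poisson_noise Apply Poisson observation noise.
#' @param seed Optional RNG seed (noise only).
#' @param post_drop_fraction Post-event visit level as a fraction of
#'   baseline before recovery (must stay below the 0.9 recovery fraction).
#' @return Long data frame `unit_id,date,poi_class,visits`.
#' @export
generate_visit_series <- function(table, baseline_level = 20,
                                  config = preprocess_config(),
                                  poisson_noise = FALSE, seed = NULL,
                                  post_drop_fraction = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(post_drop_fraction >= 0, post_drop_fraction < 0.9)
  dates <- seq(config$baseline_start, config$window_end + config$half_window,
               by = "day")
  nd <- length(dates)
  base <- rep_len(baseline_level, nrow(table))
  out <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    B <- base[i]
    raw <- rep(post_drop_fraction * B, nd)
    raw[dates <= config$baseline_end] <- B
    if (!table$censored[i]) {
      r_day <- config$week_origin + round(7 * table$duration_weeks[i]) - 1L
      step <- r_day - 2L
      raw[dates >= step] <- B
    }
    if (poisson_noise) raw <- stats::rpois(nd, raw)
    out[[i]] <- data.frame(unit_id = table$unit_id[i], date = dates,
                           poi_class = "essential", visits = raw,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate sociodemographic attributes with a planted disparity
#'
#' Late-recovering units (observed week above 2, i.e. outside the first
#' recovering group) receive incomes lower by the planted gaps and a
#' minority percentage higher by the planted gap, plus Gaussian noise;
#' minority percentages are clipped to `[0, 100]` and incomes to be
#' non-negative. The planted gaps are attached as the `ground_truth`
#' attribute for tests.
#'
#' @param table Recovery table with `unit_id` and `week`.
#' @param model Named list of base levels, gaps and noise SDs (see
#'   [synthetic_scenario()]).
#' @param seed Optional RNG seed.
#' @return Data frame
#'   `unit_id,median_household_income,per_capita_income,minority_pct` with
#'   a `ground_truth` attribute (gaps and the late-group indicator).
#' @export
generate_demographics <- function(table,
                                  model = synthetic_scenario()$demographic_model,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(table)
  late <- table$week > 2L
  income <- pmax(0, model$income_base - model$income_gap * late +
                   stats::rnorm(n, 0, model$income_sd))
  pci <- pmax(0, model$pci_base - model$pci_gap * late +
                stats::rnorm(n, 0, model$pci_sd))
  minority <- pmin(100, pmax(0, model$minority_base +
                               model$minority_gap * late +
                               stats::rnorm(n, 0, model$minority_sd)))
  out <- data.frame(unit_id = table$unit_id,
                    median_household_income = income,
                    per_capita_income = pci,
                    minority_pct = minority,
                    stringsAsFactors = FALSE)
  attr(out, "ground_truth") <- list(model = model, late = late)
  out
}
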
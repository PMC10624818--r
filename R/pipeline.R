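#' Convert seed-set percentages to sizes
#'
#' Half-up rounding of `n * p / 100` with a minimum of 1 (so, e.g., 1%, 3%,
#' 5% and 10% of 2010 units give 20, 60, 101 and 201).
#'
#' @param n Number of units.
#' @param percents Percentages in `(0, 100]`.
#' @return Integer vector of seed-set sizes.
#' @export
percent_to_sizes <- function(n, percents) {
  stopifnot(all(percents > 0), all(percents <= 100))
  pmax(1L, as.integer(floor(n * percents / 100 + 0.5)))
}

#' Pipeline run configuration
#'
#' Bundles every stage's settings. Inputs come either from a
#' [synthetic_scenario()] or from files (edge-list CSV plus a recovery
#' durations CSV, and optionally a demographics CSV). Each stage's RNG
#' stream is derived deterministically from the global seed and the stage
#' name, so a manifest plus the global seed reproduces any stage.
#'
#' @param scenario A [synthetic_scenario()], or `NULL` when files are used.
#' @param edgelist_csv,durations_csv,demographics_csv Optional input paths
#'   (used when `scenario` is `NULL`; demographics optional either way).
#' @param dcfg A [diffusion_config()].
#' @param stage1,stage2 [ga_config()]s for calibration and seed-set
#'   optimization (seeds are overridden by derived streams).
#' @param N_percents Seed-set sizes as percentages of `n`.
#' @param baseline_runs Randomized-threshold baseline repetitions.
#' @param sensitivity_runs Repeated calibration runs for the convergence
#'   diagnostic (0 disables).
#' @param n_probe_units Probe units tracked in the convergence diagnostic.
#' @param lisa_permutations,lisa_alpha LISA inference settings.
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @param seed Global RNG seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = synthetic_scenario(),
                       edgelist_csv = NULL, durations_csv = NULL,
                       demographics_csv = NULL,
                       dcfg = diffusion_config(),
                       stage1 = ga_config(max_generations = 2000L),
                       stage2 = ga_config(max_generations = 500L,
                                          stop_at_loss = NULL),
                       N_percents = c(1, 3, 5, 10),
                       baseline_runs = 1000L,
                       sensitivity_runs = 0L,
                       n_probe_units = 10L,
                       lisa_permutations = 999L,
                       lisa_alpha = 0.05,
                       out_dir = NULL,
                       seed = 1L) {
  if (is.null(scenario) && (is.null(edgelist_csv) || is.null(durations_csv)))
    stop("either a scenario or edgelist_csv + durations_csv must be given")
  structure(list(scenario = scenario, edgelist_csv = edgelist_csv,
                 durations_csv = durations_csv,
                 demographics_csv = demographics_csv,
                 dcfg = dcfg, stage1 = stage1, stage2 = stage2,
                 N_percents = N_percents, baseline_runs = baseline_runs,
                 sensitivity_runs = sensitivity_runs,
                 n_probe_units = n_probe_units,
                 lisa_permutations = lisa_permutations,
                 lisa_alpha = lisa_alpha,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the end-to-end recovery-diffusion analysis
#'
#' Orchestrates input generation (or loading), contiguity-graph
#' construction, threshold calibration against the empirical weekly states,
#' the randomized-threshold baseline, weekly recovery curves, seed-set
#' optimization for every configured size, LISA clustering of the
#' calibrated thresholds, and (when demographics are available) the
#' disparity summary. Returns a manifest of every per-stage summary;
#' artifacts are additionally written under `cfg$out_dir` when set.
#'
#' @param cfg A [run_config()].
#' @return The manifest, a list of class `run_manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage_fail <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(seed = cfg$seed, created = format(Sys.time(), "%Y-%m-%d"))

  # --- inputs -------------------------------------------------------------
  demo <- NULL
  if (!is.null(cfg$scenario)) {
    scen <- cfg$scenario
    scen$seed <- derive_seed(cfg$seed, "scenario")
    units <- stage_fail("synth", generate_units(scen))
    g <- stage_fail("graph", build_contiguity_graph(units, "queen"))
    gt <- stage_fail("synth", generate_ground_truth(scen, g, cfg$dcfg))
    table <- gt$table
    demo <- generate_demographics(table, scen$demographic_model,
                                  seed = derive_seed(cfg$seed, "demographics"))
    manifest$scenario <- list(rows = scen$rows, cols = scen$cols,
                              layout = scen$layout,
                              zero_seed_fraction = scen$zero_seed_fraction,
                              noise = scen$noise)
  } else {
    g <- stage_fail("graph", read_edgelist_csv(cfg$edgelist_csv))
    table <- stage_fail("preprocess", read_recovery_csv(cfg$durations_csv))
    if (!is.null(cfg$demographics_csv))
      demo <- utils::read.csv(cfg$demographics_csv,
                              colClasses = c(unit_id = "character"))
  }
  st <- graph_stats(g)
  manifest$graph <- list(n = st$n, m = st$m, avg_degree = st$avg_degree,
                         density = st$density)

  # --- stage 1: calibration ----------------------------------------------
  empirical <- stage_fail("calibrate",
                          states_from_durations(table, g$vertices, cfg$dcfg$T))
  # the first recovering group (discretized week 2) is pinned at zero
  zero_mask <- table$week[match(g$vertices, table$unit_id)] == 2L
  cfg$stage1$seed <- derive_seed(cfg$seed, "stage1")
  cal <- stage_fail("calibrate",
                    calibrate_thresholds(g, empirical, zero_mask,
                                         cfg$stage1, cfg$dcfg))
  bl <- stage_fail("baseline",
                   randomized_baseline(g, empirical, zero_mask,
                                       cfg$baseline_runs, cfg$dcfg,
                                       seed = derive_seed(cfg$seed, "baseline")))
  curves <- weekly_recovery_difference(empirical, cal$simulated)
  mom <- threshold_moments(cal$tau_star)
  manifest$stage1 <- list(final_loss = cal$final_loss,
                          initial_loss = cal$ga$initial_loss,
                          generations = cal$ga$generations,
                          baseline_mean_loss = bl$mean_loss,
                          zero_mask_count = sum(zero_mask),
                          tau_mean = unname(mom["mean"]),
                          tau_variance = unname(mom["variance"]),
                          affected_at_horizon =
                            affected_at_horizon(cal$simulated))
  manifest$weekly <- curves

  # --- stage 2: recovery multipliers --------------------------------------
  n <- st$n
  Ns <- percent_to_sizes(n, cfg$N_percents)
  stage2 <- vector("list", length(Ns))
  for (k in seq_along(Ns)) {
    cfg$stage2$seed <- derive_seed(cfg$seed, paste0("stage2_N", Ns[k]))
    ms <- stage_fail("multipliers",
                     optimize_multipliers(g, cal$tau_star, Ns[k],
                                          cfg$stage2, cfg$dcfg))
    stage2[[k]] <- list(N = ms$N,
                        recovered_at_T = ms$recovered_at_T,
                        baseline_recovered = ms$baseline_recovered,
                        increment_pct = increment_rate(ms$baseline_recovered,
                                                       ms$recovered_at_T),
                        members = ms$members)
  }
  names(stage2) <- paste0("N", Ns)
  manifest$stage2 <- stage2

  # --- diagnostics ---------------------------------------------------------
  lisa <- stage_fail("lisa",
                     local_morans(g, cal$tau_star$values,
                                  cfg$lisa_permutations, cfg$lisa_alpha,
                                  seed = derive_seed(cfg$seed, "lisa")))
  manifest$lisa <- as.list(table(factor(lisa$category,
                                        levels = c("HH", "HL", "LH", "LL",
                                                   "not-significant"))))
  if (cfg$sensitivity_runs > 1L) {
    runs <- lapply(seq_len(cfg$sensitivity_runs), function(r) {
      c1 <- cfg$stage1
      c1$seed <- derive_seed(cfg$seed, paste0("sensitivity", r))
      calibrate_thresholds(g, empirical, zero_mask, c1, cfg$dcfg)$tau_star
    })
    probes <- sort(sample(which(!zero_mask),
                          min(cfg$n_probe_units, sum(!zero_mask))))
    conv <- threshold_convergence(runs, probes)
    manifest$sensitivity <- list(runs = cfg$sensitivity_runs,
                                 probe_units = g$vertices[probes],
                                 final_cumulative_mean = conv[nrow(conv), ])
  }
  if (!is.null(demo)) {
    best <- stage2[[length(stage2)]]
    disp <- stage_fail("report", disparity_summary(best$members, demo))
    manifest$disparity <- lapply(disp[disparity_attrs], function(a)
      list(multiplier_median = unname(a$multiplier["median"]),
           complement_median = unname(a$complement["median"]),
           median_diff = a$median_diff))
  }

  class(manifest) <- "run_manifest"
  if (!is.null(cfg$out_dir)) write_manifest(manifest, g, table, cal, lisa, cfg)
  manifest
}

write_manifest <- function(manifest, g, table, cal, lisa, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  write_edgelist_csv(g, p("edges.csv"))
  write_graph_stats_json(graph_stats(g), p("graph_stats.json"))
  write_recovery_csv(table, p("recovery.csv"))
  write_tau_csv(cal$tau_star, g$vertices, p("tau_star.csv"))
  write_ga_trace_csv(cal$ga, p("stage1_trace.csv"))
  write_lisa_csv(lisa, p("lisa.csv"))
  for (nm in names(manifest$stage2))
    utils::write.csv(data.frame(unit_id = manifest$stage2[[nm]]$members),
                     p(paste0("multipliers_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  out <- manifest
  out$weekly <- NULL
  jsonlite::write_json(unclass(out), p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(manifest$weekly, p("weekly_curves.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(cfg$out_dir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest: n = ", x$graph$n, ", stage-1 loss ",
      x$stage1$final_loss, ", seed sets: ",
      paste(names(x$stage2), collapse = ", "), ">\n", sep = "")
  invisible(x)
}
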
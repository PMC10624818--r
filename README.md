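# recoverynet

Post-disaster community recovery spreads between neighboring areas: a
neighborhood tends to return to its normal level of activity once enough of
the areas around it have. **recoverynet** models this process as a
deterministic threshold (complex-contagion) diffusion on a spatial
contiguity network, calibrates the per-unit thresholds from observed weekly
recovery states, and then searches for the small set of *recovery
multipliers* — units whose early recovery most accelerates the recovery of
the whole community.

It is written for analysts of disaster recovery working with
mobility-derived population-activity data (daily point-of-interest visit
counts per spatial unit, e.g. census block groups), but every stage also
runs on fully synthetic inputs with known ground truth.

## The model

Spatial units are the vertices of an undirected contiguity graph
`G = (V, E)` (queen contiguity by default: units are neighbors if their
polygons share an edge *or* a vertex). Each unit `i` carries a threshold
`τ_i ∈ [0, 1]` and a binary state `S_t^(i) ∈ {0 = affected, 1 = recovered}`
over weeks `t = 0, …, 14`. All units are affected at `t = 0`; states update
synchronously and are absorbing:

```
S_{t}^(i) = 1   if   S_{t-1}^(i) = 1   or   ( Σ_{j ∈ N(i)} S_{t-1}^(j) ) / |N(i)|  ≥  τ_i
```

Units observed to recover in under two weeks are pinned at `τ_i = 0` and
form the first recovering group (week 2). The remaining thresholds are
estimated by minimizing the 0–1 loss

```
L(S, Ŝ) = Σ_{t=1..14} Σ_i  I( S_t^(i) ≠ Ŝ_t^(i) )
```

between the observed trajectory `S` (encoded from recovery durations,
right-censored at 14 weeks) and the simulated trajectory `Ŝ`, using a
deliberately classical genetic algorithm (fitness `1/L`, elitist pair,
roulette-wheel selection, single-point crossover, one-position 50/50
mutation). A second optimization stage holds the calibrated `τ*` fixed and
searches over size-`N` seed sets `M^N` (units recovered at `t = 0`) for the
set maximizing the number of recovered units at the horizon. Local Moran's
I (LISA) clusters the calibrated thresholds into High-Low / Low-High
hotspots, and disparity summaries contrast the multipliers'
sociodemographics with the rest of the community.

Recovery durations themselves are derived from daily visit counts: a
pre-event baseline (mean daily visits over a three-week window), a centred
7-day moving average, and recovery declared on the first day the smoothed
series holds at ≥ 90% of baseline for 3 consecutive days.

## Worked example

A synthetic 6 × 6 lattice with 37% planted zero-threshold units and
right-censoring retained:

```r
library(recoverynet)

scen  <- synthetic_scenario(rows = 6, cols = 6, seed = 11,
                            ensure_saturation = FALSE)
units <- generate_units(scen)
g     <- build_contiguity_graph(units, rule = "queen")
graph_stats(g)
#> n = 36, m = 110, k = 6.111, d = 0.175

gt  <- generate_ground_truth(scen, g)
emp <- states_from_durations(gt$table, g$vertices)
cal <- calibrate_thresholds(g, emp, gt$zero_mask,
                            ga_config(max_generations = 3000, seed = 1))
cal
#> <calibration_result: final loss 20 after 3000 generations>
affected_at_horizon(cal$simulated)
#> [1] 9
randomized_baseline(g, emp, gt$zero_mask, n_runs = 1000, seed = 3)$mean_loss
#> [1] 106.849

ms <- optimize_multipliers(g, cal$tau_star, N = 2,
                           ga_config(max_generations = 500, seed = 2,
                                     stop_at_loss = NULL))
increment_rate(ms$baseline_recovered, ms$recovered_at_T)
#> [1] 5.88
```

Reading: the calibrated diffusion model reproduces the observed 36 × 14
weekly state table up to 20 cell disagreements (a randomized-threshold
model averages ≈ 107), leaves 9 units unrecovered at week 14, and seeding
the right 2 units as recovered from the start raises the final recovered
count by 5.88% over the best randomly chosen pair.

The full pipeline — preprocessing, graph, calibration, baseline, seed-set
optimization for several `N`, LISA and disparity summaries — is one call:

```r
man <- run_pipeline(run_config(scenario = scen, seed = 1L,
                               out_dir = "out"))
```

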
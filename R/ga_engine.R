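#' Genetic-algorithm configuration
#'
#' A deliberately classical GA: fitness is the reciprocal of the loss,
#' selection keeps the elite pair and fills the rest of the population by
#' fitness-proportional (roulette-wheel) draws, crossover is single-point,
#' and mutation touches one uniformly chosen position which is kept with
#' probability `mutation_keep_prob` and otherwise resampled.
#'
#' @param population_size Even population size `eta` (study default 10).
#' @param max_generations Generation budget `MAX` (study defaults: 10000
#'   for threshold calibration, 2000 for seed-set optimization).
#' @param mutation_keep_prob Probability the mutated position is unchanged.
#' @param seed Optional RNG seed; identical seeds give identical runs.
#' @param stop_at_loss Stop early once the best loss reaches this value
#'   (default 0, the perfect fit); `NULL` disables early stopping.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 10L, max_generations = 10000L,
                      mutation_keep_prob = 0.5, seed = NULL,
                      stop_at_loss = 0) {
  population_size <- as.integer(population_size)
  max_generations <- as.integer(max_generations)
  stopifnot(population_size >= 2L, population_size %% 2L == 0L,
            max_generations >= 0L,
            mutation_keep_prob >= 0, mutation_keep_prob <= 1)
  structure(list(population_size = population_size,
                 max_generations = max_generations,
                 mutation_keep_prob = mutation_keep_prob,
                 seed = seed, stop_at_loss = stop_at_loss),
            class = "ga_config")
}

#' Fitness of a loss value
#'
#' `1/loss` for positive losses; a zero loss receives the finite sentinel
#' fitness 2, strictly above the largest attainable reciprocal (`1/1`), so
#' perfect chromosomes always rank first.
#'
#' @param loss Non-negative numeric vector of losses.
#' @return Numeric vector of fitness values.
#' @export
evaluate_fitness <- function(loss) {
  if (any(loss < 0)) stop("loss must be non-negative")
  ifelse(loss == 0, 2, 1 / loss)
}

#' Selection operator
#'
#' The two highest-fitness chromosomes (ties broken by lower index) occupy
#' the first two parent slots; the remaining `eta - 2` slots are drawn
#' fitness-proportionally with replacement (uniformly if all fitness is
#' zero).
#'
#' @param fitness Numeric fitness vector of the current population.
#' @return Integer vector of `eta` selected indices.
#' @export
ga_select <- function(fitness) {
  eta <- length(fitness)
  stopifnot(eta >= 2L)
  elite <- order(-fitness, seq_along(fitness))[1:2]
  rest <- integer(0)
  if (eta > 2L) {
    prob <- if (all(fitness == 0)) rep(1 / eta, eta) else fitness / sum(fitness)
    rest <- sample.int(eta, eta - 2L, replace = TRUE, prob = prob)
  }
  c(elite, rest)
}

#' Single-point crossover
#'
#' A crossover point `c` is drawn uniformly from the proper interior
#' `{1, ..., L-1}` and the parents' tails beyond `c` are swapped.
#'
#' @param p1,p2 Gene vectors of equal length `L >= 2`.
#' @param point Optional fixed crossover point (for testing).
#' @return List of two offspring gene vectors.
#' @export
ga_crossover <- function(p1, p2, point = NULL) {
  L <- length(p1)
  if (L < 2L || length(p2) != L) stop("parents must have equal length >= 2")
  c0 <- if (is.null(point)) sample.int(L - 1L, 1L) else as.integer(point)
  stopifnot(c0 >= 1L, c0 <= L - 1L)
  list(c(p1[seq_len(c0)], p2[(c0 + 1L):L]),
       c(p2[seq_len(c0)], p1[(c0 + 1L):L]))
}

#' Mutation operator
#'
#' Chooses one position uniformly; with probability `keep_prob` the gene is
#' unchanged, otherwise it is replaced by a draw from `sample_gene`
#' (`Uniform[0,1]` by default). At most one gene differs from the input.
#'
#' @param genes Gene vector of length `>= 1`.
#' @param keep_prob Probability of keeping the selected position.
#' @param sample_gene Function of the selected position returning a
#'   replacement gene.
#' @return Mutated gene vector.
#' @export
ga_mutate <- function(genes, keep_prob = 0.5,
                      sample_gene = function(pos) stats::runif(1)) {
  L <- length(genes)
  stopifnot(L >= 1L)
  pos <- sample.int(L, 1L)
  if (stats::runif(1) >= keep_prob) genes[pos] <- sample_gene(pos)
  genes
}

#' Chromosome codec for a real-valued threshold vector
#'
#' Genes are thresholds in `[0,1]`; masked positions are inert — operators
#' act on the full vector and the repair step re-clamps masked genes to 0.
#'
#' @param length Chromosome length (number of units).
#' @param zero_mask Logical vector of positions fixed at zero, or `NULL`.
#' @return A codec list with `random_genes`, `mutate`, `repair`,
#'   `crossover_ok` fields, used by [run_ga()].
#' @export
real_vector_codec <- function(length, zero_mask = NULL) {
  if (is.null(zero_mask)) zero_mask <- rep(FALSE, length)
  stopifnot(base::length(zero_mask) == length)
  clamp <- function(g) { g[zero_mask] <- 0; g }
  list(random_genes = function() clamp(stats::runif(length)),
       mutate = function(g, keep_prob) ga_mutate(g, keep_prob),
       repair = clamp,
       crossover_ok = length >= 2L)
}

#' Chromosome codec for a fixed-size subset of units
#'
#' Genes are `N` distinct unit indices in `1..n_units`. Single-point
#' crossover on the index vectors can duplicate members, so the repair step
#' replaces duplicates with uniformly random non-members; mutation swaps one
#' member for a random non-member with probability `1 - keep_prob`.
#'
#' @param n_units Number of units in the graph.
#' @param N Subset size.
#' @return A codec list for [run_ga()].
#' @export
subset_codec <- function(n_units, N) {
  stopifnot(N >= 1L, N <= n_units)
  repair <- function(g) {
    dup <- duplicated(g)
    if (any(dup)) {
      pool <- setdiff(seq_len(n_units), g[!dup])
      g[dup] <- sample(pool, sum(dup))
    }
    g
  }
  list(random_genes = function() sample.int(n_units, N),
       mutate = function(g, keep_prob)
         ga_mutate(g, keep_prob, sample_gene = function(pos) {
           pool <- setdiff(seq_len(n_units), g)
           if (length(pool) == 0L) g[pos] else sample(pool, 1L)
         }),
       repair = repair,
       crossover_ok = N >= 2L)
}

#' Run the genetic algorithm
#'
#' Initializes `eta` random chromosomes, then iterates selection ->
#' crossover -> mutation for up to `max_generations` generations, copying
#' the elite pair into the next generation unmodified (which makes the
#' best-loss trace non-increasing). Fully reproducible given `cfg$seed`.
#'
#' @param objective Function mapping a gene vector to a non-negative loss.
#' @param codec A codec such as [real_vector_codec()] or [subset_codec()].
#' @param cfg A [ga_config()].
#' @return List of class `ga_result`: `best_genes`, `best_loss`, `trace`
#'   (data frame `generation,best_loss,mean_loss,elapsed_s`),
#'   `initial_loss`, `final_loss`, `delta_L` (loss descent per generation),
#'   `R` (mean seconds per generation), `generations`,
#'   `initial_population_losses`.
#' @export
run_ga <- function(objective, codec, cfg = ga_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  eta <- cfg$population_size
  pop <- lapply(seq_len(eta), function(i) codec$random_genes())
  losses <- vapply(pop, objective, 0)
  if (any(losses < 0)) stop("objective returned a negative loss")
  init_losses <- losses
  initial_loss <- min(losses)
  best_i <- which.min(losses)
  best <- list(genes = pop[[best_i]], loss = losses[best_i])

  gens <- cfg$max_generations
  trace <- list(generation = integer(gens), best_loss = numeric(gens),
                mean_loss = numeric(gens), elapsed_s = numeric(gens))
  ran <- 0L
  stop_now <- !is.null(cfg$stop_at_loss) && best$loss <= cfg$stop_at_loss
  if (gens > 0L && !stop_now) {
    for (th in seq_len(gens)) {
      t0 <- proc.time()[["elapsed"]]
      fit <- evaluate_fitness(losses)
      sel <- ga_select(fit)
      new_pop <- vector("list", eta)
      new_losses <- numeric(eta)
      # elite pair survives unmodified, cached losses reused
      new_pop[1:2] <- pop[sel[1:2]]
      new_losses[1:2] <- losses[sel[1:2]]
      if (eta > 2L) {
        for (p in seq.int(3L, eta, by = 2L)) {
          pa <- pop[[sel[p]]]; pb <- pop[[sel[p + 1L]]]
          off <- if (isTRUE(codec$crossover_ok)) ga_crossover(pa, pb)
                 else list(pa, pb)
          for (k in 1:2) {
            g <- codec$repair(codec$mutate(off[[k]], cfg$mutation_keep_prob))
            new_pop[[p + k - 1L]] <- g
            new_losses[p + k - 1L] <- objective(g)
          }
        }
      }
      pop <- new_pop; losses <- new_losses
      gen_best <- which.min(losses)
      if (losses[gen_best] < best$loss)
        best <- list(genes = pop[[gen_best]], loss = losses[gen_best])
      ran <- th
      trace$generation[th] <- th
      trace$best_loss[th] <- losses[gen_best]
      trace$mean_loss[th] <- mean(losses)
      trace$elapsed_s[th] <- proc.time()[["elapsed"]] - t0
      if (!is.null(cfg$stop_at_loss) && best$loss <= cfg$stop_at_loss) break
    }
  }
  trace <- data.frame(generation = trace$generation[seq_len(ran)],
                      best_loss = trace$best_loss[seq_len(ran)],
                      mean_loss = trace$mean_loss[seq_len(ran)],
                      elapsed_s = trace$elapsed_s[seq_len(ran)])
  final_loss <- best$loss
  structure(list(best_genes = best$genes, best_loss = best$loss,
                 trace = trace,
                 initial_loss = initial_loss, final_loss = final_loss,
                 delta_L = if (ran > 0L) (initial_loss - final_loss) / ran
                           else 0,
                 R = if (ran > 0L) mean(trace$elapsed_s) else NA_real_,
                 generations = ran,
                 initial_population_losses = init_losses),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result: initial loss ", x$initial_loss, " -> final loss ",
      x$final_loss, " in ", x$generations, " generations>\n", sep = "")
  invisible(x)
}

#' Performance index of a GA run
#'
#' The loss descent rate per generation divided by the runtime per
#' generation, `P = delta_L / R`. Hardware-dependent through `R`.
#'
#' @param x A `ga_result`, or the loss descent rate `delta_L` directly.
#' @param R Runtime per generation in seconds (required when `x` is
#'   numeric).
#' @return The performance index `P`.
#' @export
performance_index <- function(x, R = NULL) {
  if (inherits(x, "ga_result")) { R <- x$R; x <- x$delta_L }
  if (is.null(R) || is.na(R) || R <= 0) stop("runtime per generation must be positive")
  x / R
}

#' Write a GA trace as CSV
#'
#' @param result A `ga_result`.
#' @param path Output path (`generation,best_loss,mean_loss,elapsed_s`).
#' @return `path`, invisibly.
#' @export
write_ga_trace_csv <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
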
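#' Local Moran's I with conditional-permutation inference
#'
#' Computes, for each unit, the local spatial-autocorrelation statistic
#' `I_i = z_i * sum_j w_ij z_j` on standardized values with row-standardized
#' contiguity weights (`w_ij = 1/deg_i` for neighbors), a conditional
#' permutation pseudo p-value (the unit's own value is held fixed while its
#' neighbors' values are drawn without replacement from the remaining
#' units), and the Moran-scatterplot quadrant. High-Low (HL) units have
#' above-mean values amid below-mean neighborhoods; Low-High (LH) the
#' converse. The `category` column keeps the quadrant only where the pseudo
#' p-value is at most `alpha`.
#'
#' @param g A `contiguity_graph`.
#' @param values Numeric vector aligned to `g`'s vertices.
#' @param n_permutations Conditional permutations per unit (default 999).
#' @param alpha Pseudo-significance level (default 0.05).
#' @param seed Optional RNG seed.
#' @return Data frame `unit_id,local_i,pseudo_p,quadrant,category`. A
#'   constant value field (or an isolate) yields `NA` statistics and
#'   `not-significant`.
#' @export
local_morans <- function(g, values, n_permutations = 999L, alpha = 0.05,
                         seed = NULL) {
  n <- length(g$vertices)
  stopifnot(length(values) == n, n_permutations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(mean((values - mean(values))^2))
  out <- data.frame(unit_id = g$vertices, local_i = NA_real_,
                    pseudo_p = NA_real_, quadrant = NA_character_,
                    category = "not-significant",
                    stringsAsFactors = FALSE)
  if (s == 0) return(out)
  z <- (values - mean(values)) / s
  for (i in seq_len(n)) {
    nb <- g$adj[[i]]
    deg <- length(nb)
    if (deg == 0L) next
    lag <- mean(z[nb])
    I <- z[i] * lag
    others <- z[-i]
    perm_lag <- vapply(seq_len(n_permutations), function(r)
      mean(sample(others, deg)), 0)
    perm_I <- z[i] * perm_lag
    greater <- sum(perm_I >= I)
    lesser <- sum(perm_I <= I)
    p <- (min(greater, lesser) + 1) / (n_permutations + 1)
    quad <- if (z[i] > 0 && lag > 0) "HH"
            else if (z[i] > 0) "HL"
            else if (lag > 0) "LH"
            else "LL"
    out$local_i[i] <- I
    out$pseudo_p[i] <- p
    out$quadrant[i] <- quad
    out$category[i] <- if (p <= alpha) quad else "not-significant"
  }
  out
}

tau_matrix_from_runs <- function(runs) {
  vals <- lapply(runs, function(r)
    if (inherits(r, "threshold_vector")) r$values else as.numeric(r))
  len <- unique(lengths(vals))
  if (length(len) != 1L) stop("runs differ in length")
  do.call(rbind, vals)
}

#' Run-to-run convergence of calibrated thresholds
#'
#' For each probe unit, the cumulative (running) mean of its calibrated
#' threshold across repeated optimization runs — the sensitivity diagnostic
#' showing that per-unit thresholds stabilize as runs accumulate.
#'
#' @param runs List (length `>= 2`) of [threshold_vector()]s or numeric
#'   vectors from repeated calibration runs.
#' @param probe_units Integer indices (or names, when the vectors are
#'   named) of the units to track.
#' @return Matrix `runs x probes` of cumulative means, with probe columns.
#' @export
threshold_convergence <- function(runs, probe_units) {
  stopifnot(length(runs) >= 2L)
  m <- tau_matrix_from_runs(runs)
  sub <- m[, probe_units, drop = FALSE]
  cm <- apply(sub, 2L, function(x) cumsum(x) / seq_along(x))
  colnames(cm) <- if (is.character(probe_units)) probe_units
                  else paste0("unit", probe_units)
  cm
}

#' Run-to-run stability of optimized multiplier sets
#'
#' The difference of run `r` against the first run is `N` minus the size of
#' the member intersection; the series is its running mean. Identical runs
#' give zeros, disjoint runs give `N`.
#'
#' @param runs List of `multiplier_set`s (or character member vectors) with
#'   a common `N`.
#' @return Data frame `run,difference,cumulative_mean`.
#' @export
multiplier_set_stability <- function(runs) {
  members <- lapply(runs, function(r)
    if (inherits(r, "multiplier_set")) r$members else as.character(r))
  Ns <- unique(lengths(members))
  if (length(Ns) != 1L) stop("runs have mixed N")
  N <- Ns
  ref <- members[[1L]]
  d <- vapply(members, function(mm) N - length(intersect(mm, ref)), 0)
  data.frame(run = seq_along(d), difference = d,
             cumulative_mean = cumsum(d) / seq_along(d))
}

disparity_attrs <- c("median_household_income", "per_capita_income",
                     "minority_pct")

#' Sociodemographic disparity between multipliers and the rest
#'
#' For median household income, per-capita income and minority percentage,
#' summarizes (quartiles and median) the multiplier set against its
#' complement and reports the difference of medians (multiplier minus
#' complement).
#'
#' @param multipliers A `multiplier_set` or character vector of unit ids.
#' @param demo Demographics data frame
#'   `unit_id,median_household_income,per_capita_income,minority_pct`
#'   covering every unit.
#' @return List of class `disparity_summary`: per attribute a list with
#'   `multiplier` and `complement` quartile summaries and `median_diff`;
#'   plus `n_multiplier`, `n_complement`, `complement_empty`.
#' @export
disparity_summary <- function(multipliers, demo) {
  members <- if (inherits(multipliers, "multiplier_set")) multipliers$members
             else as.character(multipliers)
  stopifnot(all(disparity_attrs %in% names(demo)), "unit_id" %in% names(demo))
  missing <- setdiff(members, demo$unit_id)
  if (length(missing) > 0L)
    stop("demographics missing for units: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  in_set <- demo$unit_id %in% members
  q <- function(x) if (length(x) == 0L) c(q25 = NA_real_, median = NA_real_,
                                          q75 = NA_real_)
       else stats::setNames(stats::quantile(x, c(.25, .5, .75), names = FALSE),
                            c("q25", "median", "q75"))
  out <- lapply(disparity_attrs, function(a) {
    ms <- q(demo[[a]][in_set]); cs <- q(demo[[a]][!in_set])
    list(multiplier = ms, complement = cs,
         median_diff = unname(ms["median"] - cs["median"]))
  })
  names(out) <- disparity_attrs
  out$n_multiplier <- sum(in_set)
  out$n_complement <- sum(!in_set)
  out$complement_empty <- sum(!in_set) == 0L
  class(out) <- "disparity_summary"
  out
}

#' @export
print.disparity_summary <- function(x, ...) {
  cat("<disparity_summary: ", x$n_multiplier, " multipliers vs ",
      x$n_complement, " others>\n", sep = "")
  for (a in disparity_attrs)
    cat("  ", a, ": median ", signif(x[[a]]$multiplier["median"], 6), " vs ",
        signif(x[[a]]$complement["median"], 6), " (diff ",
        signif(x[[a]]$median_diff, 6), ")\n", sep = "")
  invisible(x)
}

#' Mean and population variance of a threshold vector
#'
#' Moments are taken over all units, fixed-zero entries included; the
#' variance uses the `1/n` (population) convention.
#'
#' @param tau A [threshold_vector()] or numeric vector.
#' @return Named numeric vector `c(mean, variance)`.
#' @export
threshold_moments <- function(tau) {
  v <- if (inherits(tau, "threshold_vector")) tau$values else as.numeric(tau)
  stopifnot(length(v) >= 1L)
  c(mean = mean(v), variance = mean((v - mean(v))^2))
}

#' Write a LISA result as CSV
#'
#' @param lisa Data frame from [local_morans()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lisa_csv <- function(lisa, path) {
  utils::write.csv(lisa, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
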
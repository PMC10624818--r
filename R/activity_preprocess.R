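#' Preprocessing configuration for visit-based recovery durations
#'
#' Defaults follow the analysis convention for a late-August landfall event:
#' a three-week pre-event baseline, a 14-week post-event window, a centred
#' 7-day moving average, and recovery declared when smoothed visits hold at
#' 90% of baseline for 3 consecutive days.
#'
#' @param baseline_start,baseline_end Closed baseline window (dates).
#' @param week_origin First day of the post-event window; durations are
#'   measured in weeks from this day (`duration = (day - origin + 1)/7`).
#' @param window_end Last day a recovery can be declared; units not
#'   recovered by then are right-censored at 14 weeks.
#' @param recovery_fraction Fraction of baseline that must be sustained.
#' @param run_days Number of consecutive qualifying days required.
#' @param half_window Half-width (days) of the centred moving average.
#' @param min_mean_daily_visits Units whose baseline-window mean daily
#'   visits fall below this are excluded.
#' @param poi_class Which point-of-interest class feeds the analysis.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_start = as.Date("2017-08-01"),
                              baseline_end = as.Date("2017-08-21"),
                              week_origin = as.Date("2017-08-27"),
                              window_end = as.Date("2017-12-03"),
                              recovery_fraction = 0.9,
                              run_days = 3L,
                              half_window = 3L,
                              min_mean_daily_visits = 4,
                              poi_class = "essential") {
  stopifnot(recovery_fraction > 0, recovery_fraction <= 1,
            run_days >= 1L, half_window >= 0L, min_mean_daily_visits >= 0)
  structure(list(baseline_start = as.Date(baseline_start),
                 baseline_end = as.Date(baseline_end),
                 week_origin = as.Date(week_origin),
                 window_end = as.Date(window_end),
                 recovery_fraction = recovery_fraction,
                 run_days = as.integer(run_days),
                 half_window = as.integer(half_window),
                 min_mean_daily_visits = min_mean_daily_visits,
                 poi_class = poi_class),
            class = "preprocess_config")
}

check_daily <- function(dates) {
  if (is.unsorted(dates, strictly = TRUE) ||
      (length(dates) > 1L && any(diff(as.integer(dates)) != 1L)))
    stop("series must be strictly daily")
}

#' Pre-event baseline visit level
#'
#' Arithmetic mean of daily visits over the closed baseline window.
#'
#' @param series Data frame with `date` (Date) and `visits` columns.
#' @param baseline_start,baseline_end Closed window; must be fully covered.
#' @return Mean daily visits (numeric scalar).
#' @export
compute_baseline <- function(series, baseline_start, baseline_end) {
  baseline_start <- as.Date(baseline_start); baseline_end <- as.Date(baseline_end)
  check_daily(series$date)
  win <- seq(baseline_start, baseline_end, by = "day")
  if (!all(win %in% series$date))
    stop("baseline window not covered by series")
  mean(series$visits[series$date %in% win])
}

#' Centred moving average of a daily series
#'
#' Each output day averages the `2*half_window + 1` days centred on it; days
#' whose full window extends beyond the series are dropped, so the output is
#' shorter by `2*half_window`.
#'
#' @param series Data frame with `date` and `visits` (or `value`) columns.
#' @param half_window Days on each side of the target day (default 3).
#' @return Data frame with `date` and smoothed `value`.
#' @export
moving_average <- function(series, half_window = 3L) {
  half_window <- as.integer(half_window)
  stopifnot(half_window >= 0L)
  x <- if ("visits" %in% names(series)) series$visits else series$value
  check_daily(series$date)
  w <- 2L * half_window + 1L
  if (length(x) < w) stop("series shorter than moving-average window")
  value <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  keep <- !is.na(value)
  data.frame(date = series$date[keep], value = value[keep])
}

#' Discretize a recovery duration into an analysis week
#'
#' Ceiling, then clamped into `{2..14}`: sub-two-week recoveries belong to
#' the first recovering group (week 2) and durations are right-censored at
#' week 14.
#'
#' @param duration_weeks Positive numeric vector.
#' @return Integer vector in `{2..14}`.
#' @export
week_from_duration <- function(duration_weeks) {
  pmin(pmax(as.integer(ceiling(duration_weeks)), 2L), 14L)
}

#' Recovery duration of one unit from its smoothed visit series
#'
#' The recovery day is the first day `r` in `[week_origin, window_end]` such
#' that the smoothed series is at least `recovery_fraction * baseline` on
#' `run_days` consecutive days starting at `r`. The duration in weeks is
#' `(r - week_origin + 1)/7`; if no qualifying day exists the unit is
#' right-censored at 14 weeks.
#'
#' @param smoothed Data frame with `date` and `value` (e.g. from
#'   [moving_average()]).
#' @param baseline Positive baseline level.
#' @param recovery_fraction,run_days Recovery rule parameters.
#' @param week_origin,window_end Post-event scan window (dates).
#' @return List with `duration_weeks`, `week`, `censored`, `recovery_date`.
#' @export
recovery_duration <- function(smoothed, baseline, recovery_fraction = 0.9,
                              run_days = 3L, week_origin, window_end) {
  if (baseline <= 0) stop("baseline must be positive")
  week_origin <- as.Date(week_origin); window_end <- as.Date(window_end)
  check_daily(smoothed$date)
  ok <- smoothed$value >= recovery_fraction * baseline
  # a day qualifies if it starts a run of run_days qualifying days
  runs <- ok
  if (run_days > 1L)
    for (k in seq_len(run_days - 1L))
      runs <- runs & c(ok[-seq_len(k)], rep(FALSE, k))
  scan <- smoothed$date >= week_origin & smoothed$date <= window_end
  hit <- which(runs & scan)
  if (length(hit) == 0L)
    return(list(duration_weeks = 14, week = 14L, censored = TRUE,
                recovery_date = as.Date(NA)))
  r <- smoothed$date[hit[1L]]
  d <- (as.integer(r - week_origin) + 1) / 7
  list(duration_weeks = d, week = week_from_duration(d), censored = FALSE,
       recovery_date = r)
}

#' Derive a recovery table from long-format daily visit counts
#'
#' Runs the full preprocessing chain per unit — baseline, centred moving
#' average, sustained-recovery scan, right-censoring — on the configured
#' point-of-interest class.
#'
#' @param visits Long data frame `unit_id,date,poi_class,visits`.
#' @param config A [preprocess_config()].
#' @return Data frame `unit_id,duration_weeks,week,censored,baseline_mean`.
#' @export
recovery_table_from_visits <- function(visits, config = preprocess_config()) {
  stopifnot(all(c("unit_id", "date", "visits") %in% names(visits)))
  if ("poi_class" %in% names(visits))
    visits <- visits[visits$poi_class == config$poi_class, , drop = FALSE]
  visits$date <- as.Date(visits$date)
  rows <- lapply(split(visits, visits$unit_id)[unique(visits$unit_id)],
                 function(s) {
    s <- s[order(s$date), , drop = FALSE]
    b <- compute_baseline(s, config$baseline_start, config$baseline_end)
    sm <- moving_average(s, config$half_window)
    r <- recovery_duration(sm, b, config$recovery_fraction, config$run_days,
                           config$week_origin, config$window_end)
    data.frame(unit_id = s$unit_id[1L], duration_weeks = r$duration_weeks,
               week = r$week, censored = r$censored, baseline_mean = b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Drop units with too few baseline visits
#'
#' Excludes units whose mean daily visits over the baseline window fall
#' below the threshold (default 4), mirroring the minimum-visit inclusion
#' rule applied before network construction.
#'
#' @param table Recovery table with `unit_id` and `baseline_mean` columns
#'   (as produced by [recovery_table_from_visits()]); alternatively supply
#'   `visits` and `config` to compute baselines here.
#' @param visits Optional long visits data frame used when `table` lacks a
#'   `baseline_mean` column.
#' @param min_mean_daily_visits Inclusion threshold.
#' @param config A [preprocess_config()] (baseline window, poi class).
#' @return List with `table` (kept rows), `kept`, `dropped` (counts) and
#'   `dropped_ids`.
#' @export
filter_min_visits <- function(table, visits = NULL, min_mean_daily_visits = 4,
                              config = preprocess_config()) {
  if (!"baseline_mean" %in% names(table)) {
    if (is.null(visits)) stop("need baseline_mean column or visits data")
    if ("poi_class" %in% names(visits))
      visits <- visits[visits$poi_class == config$poi_class, , drop = FALSE]
    visits$date <- as.Date(visits$date)
    bm <- vapply(split(visits, visits$unit_id), function(s)
      compute_baseline(s[order(s$date), ], config$baseline_start,
                       config$baseline_end), 0)
    table$baseline_mean <- bm[table$unit_id]
  }
  keep <- table$baseline_mean >= min_mean_daily_visits
  list(table = table[keep, , drop = FALSE],
       kept = sum(keep), dropped = sum(!keep),
       dropped_ids = table$unit_id[!keep])
}

#' Write / read a recovery table as CSV
#'
#' @param table Recovery table data frame.
#' @param path File path.
#' @return `path` (writer) or the table (reader).
#' @export
write_recovery_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recovery_csv
#' @export
read_recovery_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(unit_id = "character"))
  df$censored <- as.logical(df$censored)
  df
}
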
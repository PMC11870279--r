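#' EARS-C2 detector configuration
#'
#' Parameters of the Early Aberration Reporting System C2 statistic: a
#' 7-week baseline separated from the evaluated week by a 2-week guard band,
#' with an alarm when the current count exceeds the baseline mean by at least
#' `threshold` baseline standard deviations.
#'
#' @param baseline_len Baseline length in weeks (>= 2; default 7).
#' @param guard Guard band between baseline and evaluated week (default 2).
#' @param threshold Alarm threshold in baseline standard deviations
#'   (default 3).
#' @param min_baseline_sd Floor on the baseline standard deviation; 0 (the
#'   default) activates the flat-baseline rule instead of a floor.
#' @return A `detector_config` list.
#' @export
detector_config <- function(baseline_len = 7L, guard = 2L, threshold = 3.0,
                            min_baseline_sd = 0) {
  baseline_len <- as.integer(baseline_len); guard <- as.integer(guard)
  if (baseline_len < 2L) stop("baseline_len must be >= 2", call. = FALSE)
  if (guard < 0L) stop("guard must be nonnegative", call. = FALSE)
  if (!(threshold > 0)) stop("threshold must be positive", call. = FALSE)
  if (min_baseline_sd < 0) stop("min_baseline_sd must be nonnegative", call. = FALSE)
  structure(list(baseline_len = baseline_len, guard = guard,
                 threshold = threshold, min_baseline_sd = min_baseline_sd),
            class = "detector_config")
}

# C2 statistics for the series values at positions `eval_weeks` (0-based) of
# a municipality x week count matrix; returns list(statistic, alarm) matrices.
c2_core <- function(mat, eval_weeks, config) {
  b <- config$baseline_len; g <- config$guard
  stat <- matrix(NA_real_, nrow(mat), length(eval_weeks))
  alarm <- matrix(FALSE, nrow(mat), length(eval_weeks))
  for (j in seq_along(eval_weeks)) {
    t <- eval_weeks[j]
    base <- mat[, (t - g - b + 1L):(t - g), drop = FALSE]  # cols are weeks+1
    mu <- rowMeans(base)
    sg <- apply(base, 1L, stats::sd)
    y <- mat[, t + 1L]
    sg_eff <- pmax(sg, config$min_baseline_sd)
    flat <- sg_eff == 0
    s <- (y - mu) / sg_eff
    s[flat] <- ifelse(y[flat] > mu[flat], Inf,
                      ifelse(y[flat] < mu[flat], -Inf, 0))
    stat[, j] <- s
    alarm[, j] <- ifelse(flat, y > mu, s >= config$threshold)
  }
  list(statistic = stat, alarm = alarm)
}

#' EARS-C2 aberration detection on a weekly count series
#'
#' For each evaluable week `t` (`t >= baseline_len + guard`, 0-based), the
#' baseline is the `baseline_len` weeks ending `guard + 1` weeks before `t`;
#' the statistic is `(y_t - mean) / sd` with the sample standard deviation
#' (denominator `baseline_len - 1`), floored at `min_baseline_sd`. When the
#' baseline is perfectly flat (sd 0 and no floor) the alarm rule degenerates
#' to `y_t > mean` and the statistic is reported as `Inf` / `-Inf` / `0`.
#'
#' @param series Integer (or numeric) vector of weekly counts, week 0 first.
#' @param config A [detector_config()].
#' @return A tibble `week` (0-based), `statistic`, `alarm` — one row per
#'   evaluable week; zero rows when the series is too short.
#' @examples
#' ears_c2(c(rep(0, 9), 100))  # flat-baseline alarm at week 9
#' @export
ears_c2 <- function(series, config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  n <- length(series)
  first <- config$baseline_len + config$guard
  if (n < first + 1L) {
    return(tibble::tibble(week = integer(), statistic = double(),
                          alarm = logical()))
  }
  eval_weeks <- seq.int(first, n - 1L)
  res <- c2_core(matrix(as.numeric(series), nrow = 1L), eval_weeks, config)
  tibble::tibble(week = eval_weeks, statistic = res$statistic[1L, ],
                 alarm = res$alarm[1L, ])
}

#' Run the early-warning system over a dataset view
#'
#' Applies EARS-C2 to every municipality's weekly series and returns the
#' alarms as warning events. Two operating modes:
#' \describe{
#'   \item{backfilled}{one pass over the final series of a backfilled view.}
#'   \item{realtime (vintage)}{the warning evaluated at week `w` is computed
#'     from the snapshot as of `w` — each week judged with the data available
#'     that week, as an EWS operating weekly would.}
#'   \item{realtime (final)}{one pass over a single fixed snapshot, for the
#'     alternative reading in which warnings come from one real-time table.}
#' }
#' Missing municipality-weeks are counted as 0.
#'
#' @param x A [dataset_view] (backfilled or single-snapshot modes) or, for
#'   vintage mode, the raw event tibble from which weekly snapshots are taken.
#' @param config A [detector_config()].
#' @param source Label for the emitted warnings: `"backfilled"` or
#'   `"realtime"`.
#' @param mode `"final"` (single series per municipality) or `"vintage"`
#'   (weekly snapshots; requires the event tibble).
#' @param n_weeks Study span (weeks `0 .. n_weeks - 1`).
#' @param municipalities Municipality universe (defaults to those present).
#' @return A tibble of warnings: `municipality`, `week`, `source`,
#'   `statistic` — rows only for alarm weeks.
#' @export
run_ews <- function(x, config = detector_config(),
                    source = c("backfilled", "realtime"),
                    mode = c("final", "vintage"),
                    n_weeks = NULL, municipalities = NULL) {
  source <- match.arg(source)
  mode <- match.arg(mode)
  first <- config$baseline_len + config$guard

  if (mode == "final") {
    stopifnot(inherits(x, "dataset_view"))
    counts <- view_counts(x, n_weeks = n_weeks, municipalities = municipalities)
    if (nrow(counts) == 0 || max(counts$week) < first) {
      return(empty_warnings(source))
    }
    mat <- counts_matrix(counts)
    eval_weeks <- seq.int(first, ncol(mat) - 1L)
    res <- c2_core(mat, eval_weeks, config)
    collect_warnings(rownames(mat), eval_weeks, res, source)
  } else {
    events <- if (inherits(x, "dataset_view")) x$events else x
    check_events(events)
    if (is.null(n_weeks)) {
      n_weeks <- if (nrow(events)) max(events$encounter_week) + 1L else 0L
    }
    if (is.null(municipalities)) {
      municipalities <- sort(unique(events$municipality))
    }
    if (n_weeks < first + 1L || length(municipalities) == 0) {
      return(empty_warnings(source))
    }
    out <- lapply(seq.int(first, n_weeks - 1L), function(w) {
      snap <- snapshot_view(events, w)
      counts <- view_counts(snap, n_weeks = w + 1L,
                            municipalities = municipalities)
      mat <- counts_matrix(counts)
      res <- c2_core(mat, w, config)
      collect_warnings(rownames(mat), w, res, source)
    })
    dplyr::bind_rows(out) %>%
      dplyr::arrange(.data$municipality, .data$week)
  }
}

empty_warnings <- function(source) {
  tibble::tibble(municipality = character(), week = integer(),
                 source = character(), statistic = double())
}

counts_matrix <- function(counts) {
  wide <- tidyr::pivot_wider(counts, names_from = "week",
                             values_from = "count", values_fill = 0L)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$municipality
  # columns must be weeks 0..W-1 in order
  mat[, order(as.integer(colnames(mat))), drop = FALSE]
}

collect_warnings <- function(muns, eval_weeks, res, source) {
  idx <- which(res$alarm, arr.ind = TRUE)
  if (length(idx) == 0) return(empty_warnings(source))
  tibble::tibble(
    municipality = muns[idx[, 1L]],
    week = as.integer(eval_weeks[idx[, 2L]]),
    source = source,
    statistic = res$statistic[idx]
  ) %>% dplyr::arrange(.data$municipality, .data$week)
}
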
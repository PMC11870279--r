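#' Completeness of a municipality's recent reporting
#'
#' Completeness is the proportion of weeks in the 8-week rolling window ending
#' at (and including) the evaluation week that have any registered encounter
#' visible in the snapshot. It takes only the nine values `k/8`,
#' `k = 0 .. 8`.
#'
#' @param view A snapshot [dataset_view].
#' @param municipality Municipality id.
#' @param week Evaluation week (0-based). The window is
#'   `week - window_len + 1 .. week`.
#' @param window_len Rolling-window length in weeks (default 8).
#' @return `k / window_len`, or `NA` if the window extends before the series
#'   start (the assessment is unavailable, not an error).
#' @export
completeness <- function(view, municipality, week, window_len = 8L) {
  stopifnot(inherits(view, "dataset_view"))
  if (view$kind != "snapshot") {
    stop("completeness is defined on snapshot views", call. = FALSE)
  }
  if (week < window_len - 1L) return(NA_real_)
  ev <- view$events
  in_win <- ev$municipality == municipality &
    ev$encounter_week >= week - window_len + 1L &
    ev$encounter_week <= week &
    ev$count > 0
  k <- dplyr::n_distinct(ev$encounter_week[in_win])
  k / window_len
}

#' Timeliness of a municipality's recent reporting
#'
#' Timeliness is the proportion of encounter volume in the same 8-week rolling
#' window that was registered within `lag_cut` weeks of the encounter, out of
#' the volume visible in the snapshot. Each encounter counts once
#' (volume-weighted). Undefined (`NA`) when no volume is visible in the
#' window.
#'
#' @inheritParams completeness
#' @param lag_cut Maximum delay, in weeks, counted as timely (default 2).
#' @return Fraction in `[0, 1]`, or `NA` when the window has no visible
#'   volume or extends before the series start.
#' @export
timeliness <- function(view, municipality, week, window_len = 8L, lag_cut = 2L) {
  stopifnot(inherits(view, "dataset_view"))
  if (view$kind != "snapshot") {
    stop("timeliness is defined on snapshot views", call. = FALSE)
  }
  if (week < window_len - 1L) return(NA_real_)
  ev <- view$events
  in_win <- ev$municipality == municipality &
    ev$encounter_week >= week - window_len + 1L &
    ev$encounter_week <= week
  tot <- sum(ev$count[in_win])
  if (tot == 0) return(NA_real_)
  sum(ev$count[in_win & ev$delay <= lag_cut]) / tot
}

#' Grade the composite Data Quality Index
#'
#' A municipality-week is graded *suitable* when both indicators reach their
#' thresholds: completeness at 100% and timeliness at 80% or more (the
#' defaults). Undefined timeliness (an empty window) grades unsuitable: no
#' evidence of quality is not evidence of quality.
#'
#' @param completeness Completeness fraction(s) in `[0, 1]`.
#' @param timeliness Timeliness fraction(s), possibly `NA`.
#' @param completeness_min,timeliness_min Suitability thresholds.
#' @return Logical vector: `TRUE` = suitable.
#' @examples
#' grade_dqi(1, 0.8)      # suitable
#' grade_dqi(0.875, 1)    # unsuitable: one missing week
#' grade_dqi(1, NA)       # unsuitable: timeliness undefined
#' @export
grade_dqi <- function(completeness, timeliness,
                      completeness_min = 1.0, timeliness_min = 0.8) {
  stopifnot(all(completeness >= 0 & completeness <= 1))
  completeness >= completeness_min &
    !is.na(timeliness) & timeliness >= timeliness_min
}

#' Assess the DQI weekly for every municipality
#'
#' For each evaluation week `w` (those with a full window), builds the
#' snapshot as of `w` — each week is judged with the data available that week
#' — and computes completeness, timeliness and the suitable flag per
#' municipality.
#'
#' @param events Registry event tibble (see [simulate_registration()]).
#' @param municipalities Municipality universe; municipalities with nothing
#'   registered get completeness 0 and undefined timeliness. Defaults to
#'   the municipalities present in `events`.
#' @param n_weeks Study span; defaults to `max(encounter_week) + 1`.
#' @param weeks Evaluation weeks; defaults to all full-window weeks
#'   `window_len - 1 .. n_weeks - 1`. Partial windows at the series start are
#'   skipped, not scaled.
#' @param window_len,lag_cut Window length and timely-delay cutoff.
#' @param completeness_min,timeliness_min Suitability thresholds passed to
#'   [grade_dqi()].
#' @return A tibble `municipality`, `week`, `completeness`, `timeliness`
#'   (`NA` when undefined), `suitable`.
#' @export
assess_quality <- function(events, municipalities = NULL, n_weeks = NULL,
                           weeks = NULL, window_len = 8L, lag_cut = 2L,
                           completeness_min = 1.0, timeliness_min = 0.8) {
  check_events(events)
  if (is.null(n_weeks)) {
    n_weeks <- if (nrow(events)) max(events$encounter_week) + 1L else 0L
  }
  if (is.null(municipalities)) municipalities <- sort(unique(events$municipality))
  if (is.null(weeks)) weeks <- seq.int(window_len - 1L, n_weeks - 1L)
  weeks <- weeks[weeks >= window_len - 1L & weeks <= n_weeks - 1L]

  per_week <- lapply(weeks, function(w) {
    ev <- events[events$registration_week <= w &
                   events$encounter_week >= w - window_len + 1L &
                   events$encounter_week <= w, , drop = FALSE]
    ev$delay <- ev$registration_week - ev$encounter_week
    got <- ev %>%
      dplyr::group_by(.data$municipality) %>%
      dplyr::summarise(
        completeness = dplyr::n_distinct(.data$encounter_week[.data$count > 0]) / window_len,
        timeliness = ifelse(sum(.data$count) > 0,
                            sum(.data$count[.data$delay <= lag_cut]) / sum(.data$count),
                            NA_real_),
        .groups = "drop")
    tibble::tibble(municipality = municipalities) %>%
      dplyr::left_join(got, by = "municipality") %>%
      dplyr::mutate(
        week = w,
        completeness = ifelse(is.na(.data$completeness), 0, .data$completeness))
  })
  dplyr::bind_rows(per_week) %>%
    dplyr::mutate(suitable = grade_dqi(.data$completeness, .data$timeliness,
                                       completeness_min, timeliness_min)) %>%
    dplyr::select("municipality", "week", "completeness", "timeliness", "suitable") %>%
    dplyr::arrange(.data$municipality, .data$week)
}
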
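#' Dataset views: backfilled gold standard vs real-time snapshots
#'
#' A registry is a table of events `(municipality, encounter_week,
#' registration_week, count)`. Two views of it matter for surveillance: the
#' *backfilled* view (every event, however late it was registered — the
#' retrospective gold standard) and a *snapshot* view as of week `S` (only
#' events registered by `S` — what a real-time system could see that week).
#'
#' @param events Event tibble with columns `municipality`, `encounter_week`,
#'   `registration_week`, `count`.
#' @return A `dataset_view` object: a list with `kind`
#'   (`"backfilled"`/`"snapshot"`), `as_of_week` (`NA` for backfilled) and
#'   `events` (the event rows with a computed `delay` column,
#'   `registration_week - encounter_week`).
#' @examples
#' ev <- tibble::tibble(municipality = "M0001", encounter_week = 0L,
#'                      registration_week = 2L, count = 5L)
#' backfilled_view(ev)
#' snapshot_view(ev, as_of_week = 1)  # empty: not yet registered
#' @name dataset_view
NULL

check_events <- function(events) {
  need <- c("municipality", "encounter_week", "registration_week", "count")
  if (!all(need %in% names(events))) {
    stop("events must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(events$registration_week < events$encounter_week)) {
    stop("registration_week must be >= encounter_week", call. = FALSE)
  }
  if (any(events$count < 0)) stop("event counts must be nonnegative", call. = FALSE)
  invisible(events)
}

new_dataset_view <- function(events, kind, as_of_week = NA_integer_) {
  events$delay <- events$registration_week - events$encounter_week
  structure(list(kind = kind, as_of_week = as_of_week,
                 events = tibble::as_tibble(events)),
            class = "dataset_view")
}

#' @rdname dataset_view
#' @export
backfilled_view <- function(events) {
  check_events(events)
  new_dataset_view(events, "backfilled")
}

#' @rdname dataset_view
#' @param as_of_week Week index of the snapshot: only events with
#'   `registration_week <= as_of_week` are visible.
#' @export
snapshot_view <- function(events, as_of_week) {
  check_events(events)
  as_of_week <- as.integer(as_of_week)
  keep <- events$registration_week <= as_of_week
  new_dataset_view(events[keep, , drop = FALSE], "snapshot", as_of_week)
}

#' @export
print.dataset_view <- function(x, ...) {
  hdr <- if (x$kind == "snapshot") {
    sprintf("<dataset_view: snapshot as of week %d>", x$as_of_week)
  } else "<dataset_view: backfilled>"
  cat(hdr, "\n")
  cat(sprintf("  %d event rows, %d municipalities, total count %.0f\n",
              nrow(x$events), dplyr::n_distinct(x$events$municipality),
              sum(x$events$count)))
  invisible(x)
}

#' Weekly count series from a view
#'
#' Collapses a view's events to weekly counts per municipality on the full
#' `0 .. n_weeks - 1` grid, filling weeks with no visible registration as 0 —
#' absence of registration is exactly the failure mode under study.
#'
#' @param view A [dataset_view].
#' @param n_weeks Length of the week grid; defaults to
#'   `max(encounter_week) + 1` over the view's events.
#' @param municipalities Municipality universe; defaults to those present in
#'   the view. Pass the full simulated set so municipalities with nothing yet
#'   registered appear as all-zero series.
#' @return A tibble `municipality`, `week`, `count` covering the full grid.
#' @export
view_counts <- function(view, n_weeks = NULL, municipalities = NULL) {
  stopifnot(inherits(view, "dataset_view"))
  ev <- view$events
  if (is.null(n_weeks)) {
    n_weeks <- if (nrow(ev)) max(ev$encounter_week) + 1L else 0L
  }
  if (is.null(municipalities)) municipalities <- sort(unique(ev$municipality))
  grid <- tidyr::expand_grid(municipality = municipalities,
                             week = seq_len(n_weeks) - 1L)
  agg <- ev %>%
    dplyr::group_by(.data$municipality, week = .data$encounter_week) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  grid %>%
    dplyr::left_join(agg, by = c("municipality", "week")) %>%
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
}
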
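#' Summarize a dataset view
#'
#' Totals mirroring the headline dataset description of a surveillance run:
#' total encounters, average encounters per week (reported as an integer when
#' the division is exact), and — when warnings are supplied — the median and
#' IQR of warnings per municipality (municipalities with no warnings count
#' as 0).
#'
#' @param view A [dataset_view].
#' @param n_weeks Number of study weeks (must be >= 1).
#' @param warnings Optional warning tibble from [run_ews()].
#' @param municipalities Municipality universe for the warnings-per-
#'   municipality summary; defaults to the municipalities in the view.
#' @return A list: `total_encounters`, `mean_weekly_encounters`, and (when
#'   warnings are given) `warnings_per_municipality_median` and
#'   `warnings_per_municipality_iqr` (named 25%/75% vector).
#' @examples
#' ev <- tibble::tibble(municipality = "M0001", encounter_week = 0L,
#'                      registration_week = 0L, count = 46L)
#' summarize_dataset(backfilled_view(ev), n_weeks = 23)$mean_weekly_encounters
#' @export
summarize_dataset <- function(view, n_weeks, warnings = NULL,
                              municipalities = NULL) {
  stopifnot(inherits(view, "dataset_view"))
  if (length(n_weeks) != 1 || is.na(n_weeks) || n_weeks < 1) {
    stop("n_weeks must be a positive integer", call. = FALSE)
  }
  total <- sum(view$events$count)
  avg <- total / n_weeks
  if (isTRUE(all.equal(avg, round(avg)))) avg <- round(avg)
  out <- list(total_encounters = total, mean_weekly_encounters = avg)
  if (!is.null(warnings)) {
    if (is.null(municipalities)) {
      municipalities <- sort(unique(view$events$municipality))
    }
    per_mun <- table(factor(warnings$municipality, levels = municipalities))
    out$warnings_per_municipality_median <- stats::median(as.integer(per_mun))
    out$warnings_per_municipality_iqr <-
      stats::quantile(as.integer(per_mun), c(0.25, 0.75))
  }
  out
}

split_sizes <- function(n, k) {
  sz <- rep(n %/% k, k)
  if (n %% k) sz[seq_len(n %% k)] <- sz[seq_len(n %% k)] + 1L
  sz
}

#' Build the simulation configs for a (possibly mixed) quality profile
#'
#' `"mixed"` splits the municipalities as evenly as possible across the
#' `"prompt"`, `"monthly"` and `"poor"` profiles (in that order), with
#' globally unique municipality ids. Because the quality profiles differ only
#' in registration-side parameters, the true incidence for a given seed and
#' id set is identical across profiles.
#'
#' @param profile One of `"prompt"`, `"monthly"`, `"poor"`, `"mixed"`.
#' @param n_municipalities,n_weeks,seed Passed to each group's config.
#' @param ... Further overrides for [simulation_config()].
#' @return A list of `sim_config` objects (length 1 unless mixed).
#' @export
profile_configs <- function(profile, n_municipalities, n_weeks, seed, ...) {
  if (identical(profile, "mixed")) {
    parts <- c("prompt", "monthly", "poor")
    sizes <- split_sizes(n_municipalities, length(parts))
    offs <- cumsum(c(0L, utils::head(sizes, -1L)))
    Map(function(p, sz, off) {
      quality_profile(p, n_municipalities = sz, n_weeks = n_weeks,
                      seed = seed, id_offset = off, ...)
    }, parts, sizes, offs)
  } else {
    list(quality_profile(profile, n_municipalities = n_municipalities,
                         n_weeks = n_weeks, seed = seed, ...))
  }
}

#' Run the full surveillance-quality pipeline
#'
#' Orchestrates simulate -> backfill/snapshot views -> weekly DQI assessment
#' -> EARS-C2 detection on both views -> warning concordance stratified by
#' quality -> report. With `out_dir` set, every intermediate table is written
#' as CSV plus a JSON report and a run manifest; two runs with the same
#' configuration are identical except for timestamps.
#'
#' @param profile Quality profile name (`"prompt"`, `"monthly"`, `"poor"`,
#'   `"mixed"`) used when `configs` is not given.
#' @param n_municipalities,n_weeks,seed Simulation size and master seed.
#' @param configs Optional list of `sim_config`s (overrides `profile`).
#' @param detector A [detector_config()].
#' @param window_len,lag_cut,completeness_min,timeliness_min DQI parameters.
#' @param realtime_mode `"vintage"` (week `w` judged with the week-`w`
#'   snapshot; default) or `"final"` (one fixed real-time table).
#' @param out_dir Optional output directory.
#' @param quiet Suppress per-stage log lines.
#' @return A list with `truth`, `events`, `assessments`,
#'   `warnings_backfilled`, `warnings_realtime`, `concordance` (tibble over
#'   all strata and both directions), `weekly_suitable`,
#'   `municipality_groups`, `summary`, and `manifest`.
#' @export
run_pipeline <- function(profile = "mixed", n_municipalities = 50L,
                         n_weeks = 23L, seed = 1L, configs = NULL,
                         detector = detector_config(),
                         window_len = 8L, lag_cut = 2L,
                         completeness_min = 1.0, timeliness_min = 0.8,
                         realtime_mode = c("vintage", "final"),
                         out_dir = NULL, quiet = TRUE) {
  realtime_mode <- match.arg(realtime_mode)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(configs)) {
    configs <- profile_configs(profile, n_municipalities, n_weeks, seed)
  }
  n_weeks <- configs[[1]]$n_weeks
  say("simulate: %d config group(s), seed %d", length(configs), seed)
  sims <- lapply(configs, simulate_registry)
  truth <- dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  events <- dplyr::bind_rows(lapply(sims, `[[`, "events"))
  municipalities <- sort(unique(truth$municipality))
  say("simulate: %d municipalities, %d event rows, total %.0f encounters",
      length(municipalities), nrow(events), sum(events$count))

  backfilled <- backfilled_view(events)

  say("assess: DQI on weekly snapshots (window %d, lag cut %d)",
      window_len, lag_cut)
  assessments <- assess_quality(events, municipalities = municipalities,
                                n_weeks = n_weeks, window_len = window_len,
                                lag_cut = lag_cut,
                                completeness_min = completeness_min,
                                timeliness_min = timeliness_min)

  say("detect: EARS-C2 (baseline %d, guard %d, threshold %.1f)",
      detector$baseline_len, detector$guard, detector$threshold)
  warn_bf <- run_ews(backfilled, detector, source = "backfilled",
                     mode = "final", n_weeks = n_weeks,
                     municipalities = municipalities)
  warn_rt <- run_ews(events, detector, source = "realtime",
                     mode = realtime_mode, n_weeks = n_weeks,
                     municipalities = municipalities)
  say("detect: %d backfilled warnings, %d real-time warnings",
      nrow(warn_bf), nrow(warn_rt))

  say("evaluate: concordance by stratum")
  conc <- dplyr::bind_rows(lapply(
    c("overall", "completeness", "timeliness", "suitable",
      "municipality_group"),
    function(dim) {
      dplyr::mutate(
        concordance_by_quality(warn_bf, warn_rt, assessments, dimension = dim),
        dimension = dim, .before = 1)
    }))

  weekly <- weekly_suitable_series(assessments)
  groups <- group_municipalities_by_suitable_weeks(assessments)
  summary <- summarize_dataset(backfilled, n_weeks, warnings = warn_bf,
                               municipalities = municipalities)

  report <- list(
    n_municipalities = length(municipalities),
    n_weeks = n_weeks,
    seed = seed,
    total_encounters = summary$total_encounters,
    mean_weekly_encounters = summary$mean_weekly_encounters,
    warnings_per_municipality_median = summary$warnings_per_municipality_median,
    warnings_per_municipality_iqr = as.list(summary$warnings_per_municipality_iqr),
    n_warnings = list(backfilled = nrow(warn_bf), realtime = nrow(warn_rt)),
    weekly_suitable = list(median = weekly$median, iqr = as.list(weekly$iqr)),
    concordance = conc
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("surveildq")),
    seed = seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    configs = lapply(configs, function(cfg) {
      x <- unclass(cfg); names(x)[names(x) == "id_start"] <- "id_offset"; x
    }),
    parameters = list(window_len = window_len, lag_cut = lag_cut,
                      completeness_min = completeness_min,
                      timeliness_min = timeliness_min,
                      detector = unclass(detector),
                      realtime_mode = realtime_mode),
    counts = list(truth = nrow(truth), events = nrow(events),
                  assessments = nrow(assessments),
                  warnings_backfilled = nrow(warn_bf),
                  warnings_realtime = nrow(warn_rt),
                  concordance = nrow(conc))
  )

  result <- list(truth = truth, events = events, assessments = assessments,
                 warnings_backfilled = warn_bf, warnings_realtime = warn_rt,
                 concordance = conc, weekly_suitable = weekly,
                 municipality_groups = groups, summary = summary,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      truth = file.path(out_dir, "truth.csv"),
      events = file.path(out_dir, "events.csv"),
      assessments = file.path(out_dir, "assessments.csv"),
      warnings_backfilled = file.path(out_dir, "warnings_backfilled.csv"),
      warnings_realtime = file.path(out_dir, "warnings_realtime.csv"),
      concordance = file.path(out_dir, "concordance.csv"))
    write_truth(truth, paths$truth)
    write_events(events, paths$events)
    write_assessments(assessments, paths$assessments)
    write_warnings(warn_bf, paths$warnings_backfilled)
    write_warnings(warn_rt, paths$warnings_realtime)
    readr::write_csv(conc, paths$concordance)
    manifest$paths <- paths
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         na = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    result$manifest <- manifest
  }
  say("done in %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  result
}
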
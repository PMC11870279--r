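#' Read and write pipeline tables as CSV
#'
#' Thin wrappers fixing the column contracts of each stage's interface so the
#' stages are independently runnable from files:
#' events `municipality,encounter_week,registration_week,count`; truth
#' `municipality,week,count,outbreak_flag`; assessments
#' `municipality,week,completeness,timeliness,suitable` (timeliness written
#' as an empty field when undefined); warnings
#' `municipality,week,source,statistic`; concordance summaries
#' `direction,stratum,n_reference,n_concordant,proportion`.
#'
#' @param x Table to write.
#' @param path File path.
#' @return The read tibble, or (for writers) `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_events <- function(x, path) {
  readr::write_csv(x[, c("municipality", "encounter_week",
                         "registration_week", "count")], path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, col_types = readr::cols(
    municipality = readr::col_character(),
    encounter_week = readr::col_integer(),
    registration_week = readr::col_integer(),
    count = readr::col_integer()))
  check_events(ev)
  ev
}

#' @rdname pipeline_io
#' @export
write_truth <- function(x, path) {
  out <- tibble::tibble(municipality = x$municipality, week = x$week,
                        count = x$count, outbreak_flag = as.integer(x$outbreak))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_truth <- function(path) {
  tr <- readr::read_csv(path, col_types = readr::cols(
    municipality = readr::col_character(),
    week = readr::col_integer(),
    count = readr::col_integer(),
    outbreak_flag = readr::col_integer()))
  dplyr::mutate(tr, outbreak = .data$outbreak_flag == 1L,
                outbreak_flag = NULL)
}

#' @rdname pipeline_io
#' @export
write_assessments <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_assessments <- function(path) {
  readr::read_csv(path, na = "", col_types = readr::cols(
    municipality = readr::col_character(),
    week = readr::col_integer(),
    completeness = readr::col_double(),
    timeliness = readr::col_double(),
    suitable = readr::col_logical()))
}

#' @rdname pipeline_io
#' @export
write_warnings <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_warnings <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    municipality = readr::col_character(),
    week = readr::col_integer(),
    source = readr::col_character(),
    statistic = readr::col_double()))
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Field names match [simulation_config()] arguments verbatim; unknown fields
#' are rejected so typos surface before any stage runs.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(simulation_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(simulation_config, raw)
}

#' @rdname read_sim_config
#' @param config A `sim_config` to serialize.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  names(x)[names(x) == "id_start"] <- "id_offset"
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
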
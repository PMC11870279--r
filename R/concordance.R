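#' Match warnings between two sources
#'
#' A reference warning is *concordant* when the test set contains a warning
#' for the same municipality in the same week (tolerance `tolerance_weeks`,
#' default 0 — "within the same week"). The partition of the reference set
#' into concordant / nonconcordant is exhaustive and disjoint.
#'
#' @param reference,test Warning tibbles with columns `municipality`, `week`.
#' @param tolerance_weeks Allow a match within plus/minus this many weeks
#'   (default 0).
#' @return The `reference` tibble with an added logical column `concordant`.
#' @examples
#' ref <- tibble::tibble(municipality = c("a", "a", "b"), week = c(5L, 9L, 7L))
#' tst <- tibble::tibble(municipality = c("a", "b"), week = c(5L, 8L))
#' match_warnings(ref, tst)  # 1 concordant, 2 nonconcordant
#' @export
match_warnings <- function(reference, test, tolerance_weeks = 0L) {
  stopifnot(all(c("municipality", "week") %in% names(reference)),
            all(c("municipality", "week") %in% names(test)))
  key <- function(m, w) paste(m, w, sep = "\r")
  test_keys <- unique(unlist(lapply(-tolerance_weeks:tolerance_weeks,
                                    function(d) key(test$municipality, test$week + d))))
  reference$concordant <- key(reference$municipality, reference$week) %in% test_keys
  reference
}

concordance_proportion <- function(matched) {
  n_ref <- nrow(matched)
  n_con <- sum(matched$concordant)
  tibble::tibble(n_reference = n_ref, n_concordant = n_con,
                 proportion = if (n_ref > 0) n_con / n_ref else NA_real_)
}

completeness_stratum <- function(x, window_len = 8L) {
  ifelse(is.na(x), "unassessed",
         paste0(formatC(round(x * window_len) / window_len * 100,
                        format = "fg"), "%"))
}

timeliness_stratum <- function(x) {
  lab <- paste0(seq(0, 90, 10), "-", seq(10, 100, 10), "%")
  # epsilon keeps exact bin edges (0.8 = 8/10) in their upper-closed bin
  ifelse(is.na(x), "undefined",
         lab[pmax(1L, as.integer(ceiling(x * 10 - 1e-9)))])
}

#' Concordance of warnings stratified by data quality
#'
#' Joins every warning to the real-time DQI assessment of its
#' municipality-week and computes concordance proportions per quality stratum
#' in both directions: `vs_backfilled` (backfilled warnings as reference /
#' denominator — the gold-standard reading) and `vs_realtime` (real-time
#' warnings as denominator). Warnings with no matching assessment land in an
#' explicit `"unassessed"` stratum, so stratified reference counts always sum
#' to the unstratified totals.
#'
#' @param backfilled,realtime Warning tibbles (`municipality`, `week`).
#' @param assessments DQI assessments from [assess_quality()] on the
#'   real-time data; ignored for `dimension = "overall"`.
#' @param dimension `"overall"` (a single stratum), `"completeness"` (the
#'   nine `k/8` levels), `"timeliness"` (deciles, upper-closed),
#'   `"suitable"` (binary), or `"municipality_group"` (bins of each
#'   municipality's share of suitable weeks, see
#'   [group_municipalities_by_suitable_weeks()]).
#' @param tolerance_weeks Match tolerance passed to [match_warnings()].
#' @return A tibble `direction`, `stratum`, `n_reference`, `n_concordant`,
#'   `proportion` (proportion is `NA` for empty strata).
#' @export
concordance_by_quality <- function(backfilled, realtime, assessments = NULL,
                                   dimension = c("overall", "completeness",
                                                 "timeliness", "suitable",
                                                 "municipality_group"),
                                   tolerance_weeks = 0L) {
  dimension <- match.arg(dimension)
  if (dimension != "overall" && is.null(assessments)) {
    stop("assessments are required for dimension = \"", dimension, "\"",
         call. = FALSE)
  }

  label_for <- function(warnings) {
    if (dimension == "overall") {
      return(rep("overall", nrow(warnings)))
    }
    if (dimension == "municipality_group") {
      grp <- group_municipalities_by_suitable_weeks(assessments)
      g <- grp$group[match(warnings$municipality, grp$municipality)]
      return(ifelse(is.na(g), "unassessed", as.character(g)))
    }
    i <- match(paste(warnings$municipality, warnings$week),
               paste(assessments$municipality, assessments$week))
    switch(dimension,
      completeness = ifelse(is.na(i), "unassessed",
                            completeness_stratum(assessments$completeness[i])),
      timeliness = ifelse(is.na(i), "unassessed",
                          timeliness_stratum(assessments$timeliness[i])),
      suitable = ifelse(is.na(i), "unassessed",
                        ifelse(assessments$suitable[i], "suitable", "unsuitable"))
    )
  }

  one_direction <- function(reference, test, direction) {
    matched <- match_warnings(reference, test, tolerance_weeks)
    matched$stratum <- as.character(label_for(matched))
    matched %>%
      dplyr::group_by(.data$stratum) %>%
      dplyr::summarise(n_reference = dplyr::n(),
                       n_concordant = sum(.data$concordant),
                       .groups = "drop") %>%
      dplyr::mutate(
        proportion = ifelse(.data$n_reference > 0,
                            .data$n_concordant / .data$n_reference, NA_real_),
        direction = direction)
  }

  dplyr::bind_rows(
    one_direction(backfilled, realtime, "vs_backfilled"),
    one_direction(realtime, backfilled, "vs_realtime")
  ) %>%
    dplyr::select("direction", "stratum", "n_reference", "n_concordant",
                  "proportion") %>%
    dplyr::arrange(.data$direction, .data$stratum)
}

#' Group municipalities by their share of suitable weeks
#'
#' Computes, per municipality, the fraction of assessed weeks graded suitable
#' and maps it into the five bins `<=20%`, `20-40%`, `40-60%`, `60-80%`,
#' `>=80%` (half-open, upper-closed: `[0,0.2], (0.2,0.4], ... (0.8,1]`), so
#' boundary values land deterministically.
#'
#' @param assessments Output of [assess_quality()].
#' @return A tibble `municipality`, `n_assessed`, `prop_suitable`, `group`
#'   (factor with the bin labels; `"unassessed"` for municipalities with no
#'   assessed weeks).
#' @export
group_municipalities_by_suitable_weeks <- function(assessments) {
  labs <- c("<=20%", "20-40%", "40-60%", "60-80%", ">=80%")
  assessments %>%
    dplyr::group_by(.data$municipality) %>%
    dplyr::summarise(n_assessed = dplyr::n(),
                     prop_suitable = mean(.data$suitable),
                     .groups = "drop") %>%
    dplyr::mutate(group = factor(
      ifelse(.data$n_assessed == 0, "unassessed",
             labs[pmax(1L, as.integer(ceiling(.data$prop_suitable * 5 - 1e-9)))]),
      levels = c(labs, "unassessed")))
}

#' Weekly proportion of municipalities with a suitable DQI
#'
#' For each assessed week, the share of municipalities graded suitable, with
#' the median and interquartile range of that share over the study weeks.
#'
#' @param assessments Output of [assess_quality()].
#' @return A list with `weekly` (tibble `week`, `n_assessed`, `n_suitable`,
#'   `proportion`), `median`, and `iqr` (named length-2 vector, 25% / 75%
#'   quantiles).
#' @export
weekly_suitable_series <- function(assessments) {
  weekly <- assessments %>%
    dplyr::group_by(.data$week) %>%
    dplyr::summarise(n_assessed = dplyr::n(),
                     n_suitable = sum(.data$suitable),
                     .groups = "drop") %>%
    dplyr::mutate(proportion = .data$n_suitable / .data$n_assessed)
  list(weekly = weekly,
       median = stats::median(weekly$proportion),
       iqr = stats::quantile(weekly$proportion, c(0.25, 0.75)))
}
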
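#' @importFrom stats rnbinom rpois runif rmultinom sd median quantile
#' @importFrom dplyr %>% group_by summarise ungroup filter mutate arrange select
#'   distinct left_join bind_rows n_distinct across all_of
NULL

# Deterministic substream seeds. Municipality streams are keyed by a string
# hash of the id so adding/removing municipalities never reshuffles others.
hash_id <- function(x) {
  vapply(as.character(x), function(s) {
    h <- 0
    for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

derive_seed <- function(seed, key, salt = 0L) {
  s <- ((as.numeric(seed) %% 2147483629) * 48271 +
          as.numeric(key) * 75311 +
          as.numeric(salt) * 104729) %% 2147483629
  as.integer(s)
}

#' Simulation configuration for a synthetic encounter registry
#'
#' Bundles and validates every parameter of the synthetic-data generator: the
#' true weekly incidence process (overdispersed counts with seasonality and
#' injected outbreaks) and the registration process that turns encounters into
#' registry events (reporting delays, monthly batched uploads, and postponed
#' "dropout" weeks amended months later).
#'
#' @param n_municipalities Number of municipalities to simulate.
#' @param n_weeks Length of the study span in epidemiological weeks
#'   (weeks are indexed `0 .. n_weeks - 1`).
#' @param baseline_rate Mean weekly encounter count per municipality outside
#'   outbreaks, before the seasonal multiplier. The default 1500 is of the
#'   order of the national average weekly ILI encounter volume per Brazilian
#'   municipality.
#' @param dispersion Negative-binomial size parameter; counts approach Poisson
#'   as `dispersion -> Inf` (`Inf` is accepted and uses a Poisson draw).
#' @param seasonal_amplitude Multiplicative seasonal effect in `[0, 1)`; the
#'   weekly mean is `baseline_rate * (1 + seasonal_amplitude * sin(2*pi*w/52))`.
#' @param outbreak_prob_per_week Probability that a new outbreak starts in a
#'   municipality-week with no outbreak already active.
#' @param outbreak_fold Multiplicative incidence increase during an outbreak
#'   (must exceed 1).
#' @param outbreak_duration_weeks Outbreak length in weeks.
#' @param delay_pmf Probability vector over registration delays `0 .. D` weeks;
#'   must sum to 1.
#' @param monthly_uploader_fraction Fraction of municipalities whose
#'   registrations are batched to the next "upload week" (week index
#'   congruent to 3 modulo 4), emulating monthly submission.
#' @param dropout_prob Per municipality-week probability that the week's
#'   registrations are postponed beyond the usual delay horizon and arrive as
#'   a late amendment (a uniform draw of `D + 1 .. D + 16` weeks after the
#'   encounter, within the registry's four-month amendment window).
#' @param seed Master seed; all randomness is derived from it.
#' @param id_prefix,id_offset Municipality label plumbing: ids are
#'   `sprintf("%s%04d", id_prefix, id_offset + 1:n)`. Useful when combining
#'   groups simulated under different quality profiles.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- simulation_config(n_municipalities = 5, n_weeks = 23, seed = 1)
#' @export
simulation_config <- function(n_municipalities = 50L,
                              n_weeks = 23L,
                              baseline_rate = 1500,
                              dispersion = 5,
                              seasonal_amplitude = 0.3,
                              outbreak_prob_per_week = 0.02,
                              outbreak_fold = 3,
                              outbreak_duration_weeks = 3L,
                              delay_pmf = c(0.6, 0.2, 0.1, 0.05, 0.05),
                              monthly_uploader_fraction = 0,
                              dropout_prob = 0,
                              seed = 1L,
                              id_prefix = "M",
                              id_offset = 0L) {
  cfg <- list(
    n_municipalities = as.integer(n_municipalities),
    n_weeks = as.integer(n_weeks),
    baseline_rate = baseline_rate,
    dispersion = dispersion,
    seasonal_amplitude = seasonal_amplitude,
    outbreak_prob_per_week = outbreak_prob_per_week,
    outbreak_fold = outbreak_fold,
    outbreak_duration_weeks = as.integer(outbreak_duration_weeks),
    delay_pmf = as.numeric(delay_pmf),
    monthly_uploader_fraction = monthly_uploader_fraction,
    dropout_prob = dropout_prob,
    seed = as.integer(seed),
    id_prefix = as.character(id_prefix),
    id_start = as.integer(id_offset)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid simulation config: field `%s` %s", field, why),
         call. = FALSE)
  }
  chk_pos_int <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < 1) bad(field, "must be a positive integer")
  }
  chk_pos_int("n_municipalities"); chk_pos_int("n_weeks")
  chk_pos_int("outbreak_duration_weeks")
  if (cfg$baseline_rate < 0) bad("baseline_rate", "must be nonnegative")
  if (!(cfg$dispersion > 0)) bad("dispersion", "must be positive")
  if (cfg$seasonal_amplitude < 0 || cfg$seasonal_amplitude >= 1)
    bad("seasonal_amplitude", "must lie in [0, 1)")
  for (p in c("outbreak_prob_per_week", "monthly_uploader_fraction", "dropout_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) bad(p, "must be a probability in [0, 1]")
  }
  if (cfg$outbreak_fold <= 1) bad("outbreak_fold", "must exceed 1")
  pmf <- cfg$delay_pmf
  if (length(pmf) < 1 || any(pmf < 0)) bad("delay_pmf", "entries must be nonnegative")
  if (abs(sum(pmf) - 1) > 1e-9) bad("delay_pmf", "must sum to 1 (tolerance 1e-9)")
  invisible(cfg)
}

municipality_ids <- function(cfg) {
  sprintf("%s%04d", cfg$id_prefix, cfg$id_start + seq_len(cfg$n_municipalities))
}

seasonal_multiplier <- function(weeks, amplitude) {
  1 + amplitude * sin(2 * pi * weeks / 52)
}

#' Named data-quality profiles for the registration process
#'
#' Three presets spanning the observed quality spectrum: `"prompt"`
#' (essentially all volume registered within 2 weeks, no dropout),
#' `"monthly"` (same delays but uploads batched to every 4th week), and
#' `"poor"` (most volume delayed beyond 2 weeks plus a 25% chance per
#' municipality-week that registrations slip into the late-amendment window).
#'
#' @param name One of `"prompt"`, `"monthly"`, `"poor"`.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `sim_config` with the profile's registration parameters.
#' @examples
#' quality_profile("prompt", n_municipalities = 10)
#' @export
quality_profile <- function(name, ...) {
  presets <- list(
    prompt = list(
      delay_pmf = c(0.7, 0.2, 0.1),
      monthly_uploader_fraction = 0,
      dropout_prob = 0
    ),
    monthly = list(
      delay_pmf = c(0.7, 0.2, 0.1),
      monthly_uploader_fraction = 1,
      dropout_prob = 0
    ),
    poor = list(
      delay_pmf = c(0.10, 0.10, 0.10, 0.20, 0.20, 0.15, 0.15),
      monthly_uploader_fraction = 0,
      dropout_prob = 0.25
    )
  )
  if (!is.character(name) || length(name) != 1 || !name %in% names(presets)) {
    shown <- if (is.character(name) && length(name) == 1) name else "<non-string>"
    stop(sprintf("unknown quality profile '%s'; valid profiles are: %s",
                 shown, paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(simulation_config, args)
}

#' Simulate true weekly encounter series with injected outbreaks
#'
#' Draws, for each municipality, a weekly series of true ILI-related encounter
#' counts: negative-binomial noise around a seasonal mean, multiplied by
#' `outbreak_fold` during outbreak weeks. Outbreaks start with probability
#' `outbreak_prob_per_week` in weeks with no active outbreak and last
#' `outbreak_duration_weeks`.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per municipality-week:
#'   `municipality`, `week` (0-based), `count`, `outbreak` (logical
#'   ground-truth flag).
#' @examples
#' truth <- simulate_truth(simulation_config(n_municipalities = 3, seed = 7))
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- municipality_ids(config)
  weeks <- seq_len(config$n_weeks) - 1L
  season <- seasonal_multiplier(weeks, config$seasonal_amplitude)
  keys <- hash_id(ids)

  per_mun <- lapply(seq_along(ids), function(i) {
    set.seed(derive_seed(config$seed, keys[i], salt = 1L))
    remaining <- 0L
    flags <- logical(config$n_weeks)
    counts <- integer(config$n_weeks)
    for (w in seq_len(config$n_weeks)) {
      if (remaining == 0L && runif(1) < config$outbreak_prob_per_week) {
        remaining <- config$outbreak_duration_weeks
      }
      flags[w] <- remaining > 0L
      if (remaining > 0L) remaining <- remaining - 1L
      mu <- config$baseline_rate * season[w] *
        (if (flags[w]) config$outbreak_fold else 1)
      counts[w] <- if (mu == 0) {
        0L
      } else if (is.infinite(config$dispersion)) {
        rpois(1, lambda = mu)
      } else {
        rnbinom(1, size = config$dispersion, mu = mu)
      }
    }
    tibble::tibble(municipality = ids[i], week = weeks,
                   count = counts, outbreak = flags)
  })
  dplyr::bind_rows(per_mun)
}

#' Partition true encounters into registry events with reporting delays
#'
#' Emulates how encounters enter the registry: each encounter-week's volume is
#' split across registration weeks by multinomial draws from `delay_pmf`;
#' with probability `dropout_prob` a municipality-week's whole volume is
#' instead postponed into the late-amendment window (`D+1 .. D+16` weeks after
#' the encounter, `D` the delay horizon); monthly-uploader municipalities have
#' every registration deferred to the next upload week (index congruent to 3
#' mod 4). The partition is exact: summing event counts over registration
#' weeks recovers the true count for every municipality-week.
#'
#' @param truth Output of [simulate_truth()] (columns `municipality`, `week`,
#'   `count`).
#' @param config The same [simulation_config()] used to generate `truth`.
#' @return A tibble of registry events: `municipality`, `encounter_week`,
#'   `registration_week`, `count` (rows with positive count only).
#' @examples
#' cfg <- simulation_config(n_municipalities = 2, seed = 3)
#' ev <- simulate_registration(simulate_truth(cfg), cfg)
#' @export
simulate_registration <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  need <- c("municipality", "week", "count")
  if (!all(need %in% names(truth))) {
    stop("truth must have columns municipality, week, count", call. = FALSE)
  }
  if (max(truth$week) + 1L > config$n_weeks || min(truth$week) < 0) {
    stop("truth span does not match config n_weeks", call. = FALSE)
  }
  pmf <- config$delay_pmf
  horizon <- length(pmf) - 1L
  delays <- 0:horizon

  ids <- unique(truth$municipality)
  keys <- hash_id(ids)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- truth[truth$municipality == ids[i], , drop = FALSE]
    set.seed(derive_seed(config$seed, keys[i], salt = 2L))
    monthly <- runif(1) < config$monthly_uploader_fraction
    enc <- integer(0); reg <- integer(0); cnt <- integer(0)
    for (r in seq_len(nrow(sub))) {
      w <- sub$week[r]; cc <- sub$count[r]
      dropped <- runif(1) < config$dropout_prob   # drawn even for cc = 0 to keep streams aligned
      if (cc == 0L) next
      if (dropped) {
        rw <- w + horizon + sample.int(16L, 1L)
        enc <- c(enc, w); reg <- c(reg, rw); cnt <- c(cnt, cc)
      } else {
        alloc <- as.integer(rmultinom(1, cc, pmf))
        keep <- alloc > 0L
        enc <- c(enc, rep.int(w, sum(keep)))
        reg <- c(reg, w + delays[keep])
        cnt <- c(cnt, alloc[keep])
      }
    }
    if (monthly && length(reg)) reg <- reg + (3L - reg) %% 4L
    out[[i]] <- tibble::tibble(municipality = ids[i], encounter_week = enc,
                               registration_week = reg, count = cnt)
  }
  ev <- dplyr::bind_rows(out)
  dplyr::arrange(ev, .data$municipality, .data$encounter_week,
                 .data$registration_week)
}

#' Simulate a complete registry in one call
#'
#' Convenience wrapper running [simulate_truth()] then
#' [simulate_registration()].
#'
#' @inheritParams simulate_registration
#' @return A list with elements `truth` and `events`.
#' @export
simulate_registry <- function(config) {
  truth <- simulate_truth(config)
  list(truth = truth, events = simulate_registration(truth, config))
}
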
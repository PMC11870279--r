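# Shared fixtures, built in code.

# Independent brute-force evaluation of the C2 rule, written long-hand so it
# shares no code with the package implementation.
brute_c2 <- function(y, baseline_len = 7, guard = 2, threshold = 3) {
  weeks <- c(); stats <- c(); alarms <- c()
  t <- baseline_len + guard
  while (t <= length(y) - 1) {
    base <- c()
    for (k in 1:baseline_len) base <- c(base, y[t - guard - k + 1])
    m <- sum(base) / baseline_len
    ss <- 0
    for (b in base) ss <- ss + (b - m)^2
    s <- sqrt(ss / (baseline_len - 1))
    cur <- y[t + 1]
    if (s == 0) {
      stat <- if (cur > m) Inf else if (cur < m) -Inf else 0
      al <- cur > m
    } else {
      stat <- (cur - m) / s
      al <- stat >= threshold
    }
    weeks <- c(weeks, t); stats <- c(stats, stat); alarms <- c(alarms, al)
    t <- t + 1
  }
  list(week = weeks, statistic = stats, alarm = alarms)
}

# Registry with all volume registered immediately: the perfect-quality limit.
perfect_config <- function(n = 10L, n_weeks = 23L, seed = 1L, ...) {
  simulation_config(n_municipalities = n, n_weeks = n_weeks,
                    delay_pmf = 1, dropout_prob = 0,
                    monthly_uploader_fraction = 0, seed = seed, ...)
}

# Small hand-built event table: one row per (mun, enc, reg).
make_events <- function(municipality, encounter_week, registration_week, count) {
  tibble::tibble(municipality = municipality,
                 encounter_week = as.integer(encounter_week),
                 registration_week = as.integer(registration_week),
                 count = as.integer(count))
}

# Delay distribution with a given probability mass within 2 weeks; the rest
# spread over delays 3..6.
delay_pmf_with_mass <- function(mass_within_2) {
  c(mass_within_2 * c(0.5, 0.3, 0.2), (1 - mass_within_2) * c(0.4, 0.3, 0.2, 0.1))
}

# Overall warning concordance (vs_backfilled) for one simulated registry.
overall_concordance <- function(events, n_weeks, municipalities,
                                detector = detector_config()) {
  bf <- run_ews(backfilled_view(events), detector, source = "backfilled",
                mode = "final", n_weeks = n_weeks,
                municipalities = municipalities)
  rt <- run_ews(events, detector, source = "realtime", mode = "vintage",
                n_weeks = n_weeks, municipalities = municipalities)
  m <- match_warnings(bf, rt)
  c(n_reference = nrow(m), n_concordant = sum(m$concordant))
}
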
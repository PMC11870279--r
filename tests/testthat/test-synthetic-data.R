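test_that("config validation rejects out-of-domain parameters by name", {
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(seasonal_amplitude = 1), "seasonal_amplitude")
  expect_error(simulation_config(outbreak_fold = 1), "outbreak_fold")
  expect_error(simulation_config(dropout_prob = 1.2), "dropout_prob")
  expect_error(simulation_config(delay_pmf = c(0.5, 0.4)), "delay_pmf")
  expect_error(simulation_config(delay_pmf = c(1.2, -0.2)), "delay_pmf")
  expect_error(simulation_config(n_weeks = 0), "n_weeks")
})

test_that("degenerate truth configurations behave as stated", {
  cfg <- simulation_config(n_municipalities = 5, n_weeks = 12,
                           outbreak_prob_per_week = 0, seed = 11)
  truth <- simulate_truth(cfg)
  expect_false(any(truth$outbreak))

  cfg0 <- simulation_config(n_municipalities = 5, n_weeks = 12,
                            baseline_rate = 0, outbreak_prob_per_week = 0,
                            seed = 11)
  expect_true(all(simulate_truth(cfg0)$count == 0))
})

test_that("non-outbreak counts match the analytic seasonal mean", {
  cfg <- simulation_config(n_municipalities = 100, n_weeks = 23,
                           baseline_rate = 50, dispersion = 5,
                           outbreak_prob_per_week = 0.02, seed = 20240101)
  truth <- simulate_truth(cfg)
  calm <- truth[!truth$outbreak, ]
  # oracle: per-week NB mean mu_w and variance mu_w + mu_w^2 / size
  mu_w <- cfg$baseline_rate * (1 + cfg$seasonal_amplitude * sin(2 * pi * calm$week / 52))
  var_w <- mu_w + mu_w^2 / cfg$dispersion
  z <- (mean(calm$count) - mean(mu_w)) / (sqrt(sum(var_w)) / nrow(calm))
  expect_lt(abs(z), 3)
})

test_that("registration partitions every true count exactly", {
  cfg <- simulation_config(n_municipalities = 20, n_weeks = 23,
                           delay_pmf = c(0.4, 0.2, 0.2, 0.1, 0.1),
                           monthly_uploader_fraction = 0.5,
                           dropout_prob = 0.2, seed = 99)
  reg <- simulate_registry(cfg)
  got <- dplyr::summarise(
    dplyr::group_by(reg$events, municipality, week = encounter_week),
    count = sum(count), .groups = "drop")
  truth_pos <- reg$truth[reg$truth$count > 0, c("municipality", "week", "count")]
  expect_equal(dplyr::arrange(got, municipality, week),
               dplyr::arrange(truth_pos, municipality, week),
               ignore_attr = TRUE)
  expect_true(all(reg$events$registration_week >= reg$events$encounter_week))
  expect_true(all(reg$events$count > 0))
})

test_that("all-mass-at-zero delay registers every event in its encounter week", {
  reg <- simulate_registry(perfect_config(n = 8, seed = 4))
  expect_true(all(reg$events$registration_week == reg$events$encounter_week))
})

test_that("half/half delay split matches the binomial oracle", {
  cfg <- simulation_config(n_municipalities = 30, n_weeks = 15,
                           baseline_rate = 200, delay_pmf = c(0.5, 0.5),
                           outbreak_prob_per_week = 0, seed = 7)
  ev <- simulate_registry(cfg)$events
  total <- sum(ev$count)
  frac0 <- sum(ev$count[ev$registration_week == ev$encounter_week]) / total
  se <- 0.5 / sqrt(total)
  expect_lt(abs(frac0 - 0.5), 3 * se)
})

test_that("quality profiles encode their intended registration behaviour", {
  expect_error(quality_profile("unknown"), "prompt.*monthly.*poor")

  prompt <- quality_profile("prompt")
  expect_gte(sum(prompt$delay_pmf[1:3]), 0.9)
  expect_equal(prompt$dropout_prob, 0)

  monthly <- quality_profile("monthly", n_municipalities = 6, seed = 2)
  ev <- simulate_registry(monthly)$events
  expect_true(all(ev$registration_week %% 4 == 3))

  poor <- quality_profile("poor")
  expect_gte(poor$dropout_prob, 0.2)
  expect_gt(sum(poor$delay_pmf[-(1:3)]), 0.5)
})

test_that("dropout postpones whole weeks past the delay horizon", {
  cfg <- simulation_config(n_municipalities = 5, n_weeks = 10,
                           delay_pmf = 1, dropout_prob = 1, seed = 13)
  ev <- simulate_registry(cfg)$events
  lag <- ev$registration_week - ev$encounter_week
  expect_true(all(lag >= 1 & lag <= 16))
})

test_that("with zero delay every snapshot is the backfilled past", {
  ev <- simulate_registry(perfect_config(n = 5, n_weeks = 15, seed = 6))$events
  for (w in c(0L, 7L, 14L)) {
    snap <- snapshot_view(ev, w)$events
    expect_identical(snap[names(ev)], ev[ev$encounter_week <= w, ])
  }
})

test_that("simulation is deterministic and substreams are municipality-stable", {
  cfg <- simulation_config(n_municipalities = 10, n_weeks = 20,
                           dropout_prob = 0.1, seed = 31)
  a <- simulate_registry(cfg)
  b <- simulate_registry(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$events, b$events)

  # adding municipalities must not reshuffle existing ones
  big <- simulate_truth(simulation_config(n_municipalities = 15, n_weeks = 20,
                                          dropout_prob = 0.1, seed = 31))
  shared <- unique(a$truth$municipality)
  expect_identical(a$truth, big[big$municipality %in% shared, ])
})
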
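warns <- function(m, w, source = "x") {
  tibble::tibble(municipality = m, week = as.integer(w), source = source,
                 statistic = 5)
}

test_that("warning matching partitions the reference set as expected", {
  ref <- warns(c("m1", "m1", "m2"), c(5, 9, 7))
  tst <- warns(c("m1", "m2"), c(5, 8))

  same <- match_warnings(ref, ref)
  expect_true(all(same$concordant))

  disjoint <- match_warnings(ref, warns("m9", 1))
  expect_false(any(disjoint$concordant))

  m <- match_warnings(ref, tst)
  expect_equal(sum(m$concordant), 1)
  expect_equal(sum(!m$concordant), 2)

  # a one-week tolerance recovers the (m2, 7) vs (m2, 8) near-miss
  m1 <- match_warnings(ref, tst, tolerance_weeks = 1)
  expect_equal(sum(m1$concordant), 2)
})

test_that("municipalities are grouped by their share of suitable weeks", {
  asmt <- tibble::tibble(
    municipality = rep(c("all", "none", "most"), each = 23),
    week = rep(0:22, 3),
    completeness = 1, timeliness = 1,
    suitable = rep(c(TRUE, FALSE, NA), each = 23))
  asmt$suitable[asmt$municipality == "most"] <- rep(c(TRUE, FALSE), c(14, 9))
  grp <- group_municipalities_by_suitable_weeks(asmt)
  expect_equal(as.character(grp$group[grp$municipality == "all"]), ">=80%")
  expect_equal(as.character(grp$group[grp$municipality == "none"]), "<=20%")
  expect_equal(as.character(grp$group[grp$municipality == "most"]), "60-80%")  # 14/23 = 0.609
  # exact edges land in the upper-closed bin
  expect_equal(as.character(
    group_municipalities_by_suitable_weeks(tibble::tibble(
      municipality = "edge", week = 0:4, completeness = 1, timeliness = 1,
      suitable = c(TRUE, FALSE, FALSE, FALSE, FALSE)))$group), "<=20%")
})

test_that("weekly suitable series yields per-week proportions with median and IQR", {
  all_ok <- tibble::tibble(municipality = rep(c("a", "b"), each = 3),
                           week = rep(7:9, 2), completeness = 1,
                           timeliness = 1, suitable = TRUE)
  ws <- weekly_suitable_series(all_ok)
  expect_true(all(ws$weekly$proportion == 1))
  expect_equal(ws$median, 1)
  expect_equal(unname(diff(ws$iqr)), 0)

  three <- tibble::tibble(
    municipality = rep(sprintf("m%02d", 1:10), times = 3),
    week = rep(1:3, each = 10), completeness = 1, timeliness = 1,
    suitable = c(rep(c(TRUE, FALSE), c(5, 5)),
                 rep(c(TRUE, FALSE), c(7, 3)),
                 rep(c(TRUE, FALSE), c(9, 1))))
  expect_equal(weekly_suitable_series(three)$median, 0.7)
})

test_that("a half prompt / half poor population has ~50% suitable municipalities weekly", {
  cfgs <- list(
    quality_profile("prompt", n_municipalities = 50, n_weeks = 23, seed = 60),
    quality_profile("poor", n_municipalities = 50, n_weeks = 23, seed = 60,
                    id_offset = 50))
  events <- dplyr::bind_rows(lapply(cfgs, function(cfg) simulate_registry(cfg)$events))
  asmt <- assess_quality(events, n_weeks = 23,
                         municipalities = sort(unique(events$municipality)))
  ws <- weekly_suitable_series(asmt)
  # binomial oracle at n = 100 municipalities: 3 SE ~ 0.15
  expect_true(all(abs(ws$weekly$proportion - 0.5) < 0.15))
})

test_that("stratified concordance conserves totals and directions agree on matches", {
  res <- run_pipeline(profile = "mixed", n_municipalities = 30, n_weeks = 23,
                      seed = 12)
  conc <- res$concordance
  overall <- conc[conc$dimension == "overall", ]
  for (dim in c("completeness", "timeliness", "suitable", "municipality_group")) {
    for (dir in c("vs_backfilled", "vs_realtime")) {
      strat <- conc[conc$dimension == dim & conc$direction == dir, ]
      expect_equal(sum(strat$n_reference),
                   overall$n_reference[overall$direction == dir])
      expect_equal(sum(strat$n_concordant),
                   overall$n_concordant[overall$direction == dir])
    }
  }
  # matches are symmetric: only the denominators differ between directions
  expect_equal(overall$n_concordant[overall$direction == "vs_backfilled"],
               overall$n_concordant[overall$direction == "vs_realtime"])
  expect_true(all(conc$n_concordant <= conc$n_reference))
})

test_that("the suitable stratum is more concordant than the unsuitable one (majority of seeds)", {
  wins <- 0L; valid <- 0L
  for (s in 1:5) {
    cfgs <- list(
      quality_profile("prompt", n_municipalities = 30, n_weeks = 30, seed = 300 + s),
      quality_profile("poor", n_municipalities = 30, n_weeks = 30, seed = 300 + s,
                      id_offset = 30))
    res <- run_pipeline(configs = cfgs, seed = 300 + s)
    strat <- res$concordance
    strat <- strat[strat$dimension == "suitable" &
                     strat$direction == "vs_backfilled", ]
    ps <- strat$proportion[strat$stratum == "suitable"]
    pu <- strat$proportion[strat$stratum == "unsuitable"]
    if (length(ps) == 1 && length(pu) == 1 && !is.na(ps) && !is.na(pu)) {
      valid <- valid + 1L
      if (ps > pu) wins <- wins + 1L
    }
  }
  expect_gte(valid, 3)
  expect_gt(wins / valid, 0.5)
})

test_that("perfect data quality gives full concordance in both directions", {
  res <- run_pipeline(configs = list(perfect_config(n = 10, seed = 77)), seed = 77)
  overall <- res$concordance[res$concordance$dimension == "overall", ]
  expect_true(all(overall$proportion == 1))
  expect_gt(sum(overall$n_reference), 0)
})
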
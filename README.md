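# surveildq

Data quality and early-warning concordance for syndromic surveillance.

Public-health early-warning systems (EWS) detect influenza-like-illness
(ILI) outbreaks from weekly counts of primary-health-care encounters per
municipality. The registry feeding such a system is updated unevenly:
municipalities upload late, in monthly batches, or skip weeks and amend them
months later. The dataset visible *in real time* at week *w* is therefore an
incomplete, lagged snapshot of the *backfilled* dataset that exists after
all amendments — and outbreak warnings computed on the two can disagree.

`surveildq` is for surveillance methodologists and data managers who want to
quantify that disagreement and gate an EWS on data quality. It provides:

- a **synthetic registry generator**: municipality-week encounter counts
  (negative binomial, seasonal, with injected outbreaks) pushed through a
  registration process with reporting delays, monthly batch uploads, and
  late-amended dropout weeks;
- the **Data Quality Index (DQI)** per municipality-week on an 8-week
  rolling window: *completeness* (share of window weeks with any registered
  encounter, values k/8) and *timeliness* (share of window volume registered
  within 2 weeks); a week is **suitable** iff completeness = 100% and
  timeliness ≥ 80%;
- **EARS-C2 detection**: alarm at week *t* when
  `(y_t − mean(baseline)) / sd(baseline) ≥ 3`, with a 7-week baseline and
  2-week guard band, evaluated on the backfilled series and, in real time,
  on the weekly snapshot available at each week;
- **concordance analysis**: a warning is concordant when both views raise it
  for the same municipality-week; proportions are reported with either view
  as denominator and stratified by completeness level, timeliness decile,
  suitability, and municipality groups (share of suitable weeks:
  `<=20% … >=80%`).

## Worked example

```r
library(surveildq)
res <- run_pipeline(profile = "mixed", n_municipalities = 60,
                    n_weeks = 23, seed = 2024)
dplyr::filter(res$concordance, dimension %in% c("overall", "suitable"))
```

```
# A tibble: 6 × 6
  dimension direction     stratum    n_reference n_concordant proportion
  <chr>     <chr>         <chr>            <int>        <int>      <dbl>
1 overall   vs_backfilled overall             46            3     0.0652
2 overall   vs_realtime   overall              3            3     1
3 suitable  vs_backfilled suitable             7            2     0.286
4 suitable  vs_backfilled unsuitable          39            1     0.0256
5 suitable  vs_realtime   suitable             2            2     1
6 suitable  vs_realtime   unsuitable           1            1     1
```

The mixed profile splits the 60 municipalities across `prompt`, `monthly`
and `poor` upload behaviour. Of the 46 warnings the EWS raises on the
backfilled gold standard, only 3 (6.5%) are also raised in real time —
late registration suppresses the evaluated week's count, so the real-time
detector stays silent. Concordance among warnings in *suitable*
municipality-weeks (28.6%) is an order of magnitude above the *unsuitable*
stratum (2.6%): the DQI identifies exactly the municipality-weeks whose
real-time warnings can be trusted. The weekly share of suitable
municipalities is in `res$weekly_suitable` (median 33% here — the `prompt`
third of the population), and `res$summary` reports 2,760,020 total
encounters and a median of 1 backfilled warning per municipality (IQR 0–1).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/surveildq.R run-all --profile mixed --municipalities 60 \
    --weeks 23 --seed 2024 --out out/
```

writing per-stage CSVs plus `report.json` and `manifest.json`; `simulate`,
`assess`, `detect` and `evaluate` run single stages on the CSV interfaces.

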
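---
title: "Methods: data quality and early-warning concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data quality and early-warning concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveildq)
```

## The problem

Early-warning systems (EWS) for influenza-like illness (ILI) consume weekly
counts of primary-health-care encounters per municipality. Those counts come
from an administrative registry that municipalities update on their own
schedule: some upload continuously, some in monthly batches, and some miss
weeks entirely and amend them months later. The *real-time* dataset an EWS
sees at week $w$ is therefore incomplete and lagged relative to the
*backfilled* dataset obtained after all amendments have arrived — and
warnings raised on the two can disagree.

`surveildq` implements the whole evaluation loop for this problem:

1. a synthetic registry generator whose backfilled and real-time views
   diverge in controlled, quality-dependent ways;
2. a weekly, per-municipality **Data Quality Index (DQI)** built from
   completeness and timeliness;
3. **EARS-C2** aberration detection on weekly counts;
4. **concordance analysis** of warnings between the real-time and backfilled
   views, stratified by data quality.

## Data model

The atomic record is a registry event
`(municipality, encounter_week, registration_week, count)`: `count`
encounters that occurred in `encounter_week` and first entered the registry
in `registration_week` (`registration_week >= encounter_week`; weeks are
0-based integer indices within the study span). Two views derive from the
events:

- **backfilled** — every event, however late (`backfilled_view()`);
- **snapshot as of week `S`** — only events with
  `registration_week <= S` (`snapshot_view()`).

Summing event counts over registration weeks recovers the true weekly count
exactly; this conservation is asserted throughout the test suite.

## The DQI

Both indicators are computed per municipality on an 8-week rolling window,
on the snapshot available at the evaluation week:

- **Completeness**: the proportion of the 8 window weeks with *any* visible
  registered encounter. It takes only the nine values $k/8$.
- **Timeliness**: the proportion of encounter volume in the window
  registered within 2 weeks of the encounter, out of the volume visible in
  the snapshot. Undefined when the window has no visible volume.

A municipality-week is **suitable** when completeness $= 100\%$ *and*
timeliness $\ge 80\%$ (both thresholds configurable via
`completeness_min` / `timeliness_min`).

Three points were genuinely open and are fixed here as package decisions:

- **Window alignment.** The window *ends at and includes* the evaluation
  week ($w-7 \dots w$). The DQI gates the warning evaluated at week $w$, so
  it should describe exactly the data feeding that warning.
- **Timeliness weighting and denominator.** Volume-weighted (each encounter
  counts once), and the denominator is the volume *visible in the snapshot*,
  not the eventual backfilled volume — a real-time system cannot see
  unregistered encounters. Both readings of "proportion of registries" are
  defensible; the visible-volume reading is the one a deployed system can
  compute.
- **Undefined timeliness grades unsuitable.** An empty window carries no
  evidence of quality; absence of evidence is not treated as evidence of
  quality. Likewise, partial windows at the series start are skipped rather
  than scaled, to avoid inflating completeness in the first 7 weeks.

## EARS-C2 detection

For week $t$, with baseline length $b = 7$ and guard band $g = 2$:

$$C_2(t) = \frac{y_t - \bar y_{t-g-b\,\dots\,t-g-1}}{s_{t-g-b\,\dots\,t-g-1}}$$

with $\bar y$ and $s$ the mean and sample standard deviation (denominator
$b - 1$) of the baseline window; an alarm is raised when
$C_2(t) \ge 3$. The baseline/guard/threshold values are the canonical EARS
C2 settings and are all configurable (`detector_config()`). Numerical edge
cases:

- **Flat baseline** ($s = 0$, no `min_baseline_sd` floor): the statistic is
  undefined, so the rule degenerates to "alarm iff $y_t$ exceeds the
  baseline mean", with the statistic reported as `Inf`/`-Inf`/`0`. A spike
  over a perfectly flat baseline is the clearest aberration there is.
- Series shorter than $b + g + 1$ yield an empty result, not an error.
- The statistic is invariant to adding a constant to the series and (when
  $s > 0$) to positive rescaling; both invariances are property-tested
  against a brute-force re-implementation.

Real-time detection runs in **vintage mode** by default: the warning
evaluated at week $w$ uses the snapshot *as of* $w$, reproducing an EWS that
runs weekly on whatever data exists that week. A `final` mode (one fixed
real-time table) is provided because the alternative reading is also
plausible; the two coincide exactly when all delays are zero. Missing
municipality-weeks count as zero encounters — absent registration is
precisely the failure mode under study, not missing data to impute.

Consecutive alarm weeks count as separate warnings (no episode merging),
because concordance is defined week by week.

## Concordance

A backfilled warning is *concordant* when a real-time warning exists for the
same municipality and the same week (tolerance 0 by default; a `±k`-week
tolerance exists but defaults off). Both denominators are always computed:

- `vs_backfilled` — backfilled warnings as reference (the gold-standard
  reading);
- `vs_realtime` — real-time warnings as reference.

The matched *pairs* are identical either way; only denominators differ, and
the tests assert this duality. Warnings are stratified by the real-time DQI
of their own municipality-week (suitability is a weekly property, so gating
is per municipality-week, not per municipality), with an explicit
`"unassessed"` stratum so stratified counts always sum to totals.
Completeness strata are the nine $k/8$ levels; timeliness strata are deciles
(upper-closed, so 0.8 falls in 70–80%); municipalities are also grouped by
their share of suitable weeks into `<=20%`, `20-40%`, `40-60%`, `60-80%`,
`>=80%` (half-open, upper-closed bins — an exact 80% share falls in
`60-80%`, so `>=80%` reads "strictly above").

## The synthetic registry generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is evaluated.

**True incidence.** Weekly counts per municipality are negative binomial
with mean `baseline_rate × (1 + seasonal_amplitude · sin(2πw/52))`,
multiplied by `outbreak_fold` during outbreak weeks. Outbreaks start with a
per-week probability in municipalities with no active outbreak (so
ground-truth labels stay unambiguous) and last a fixed number of weeks.
Defaults: `baseline_rate = 1500` (the order of the national average weekly
ILI encounter volume per municipality implied by ~8.6 million weekly
encounters across ~5,570 municipalities), `dispersion = 5` (administrative
count data are strongly overdispersed; Poisson is recovered as
`dispersion → Inf`), `seasonal_amplitude = 0.3`,
`outbreak_prob_per_week = 0.02`, `outbreak_fold = 3` over 3 weeks, and a
23-week study span.

**Registration.** Each encounter-week's volume is partitioned across
registration weeks by a multinomial draw from `delay_pmf`. Three
quality-degrading mechanisms are layered on top:

- *monthly uploaders*: a configurable fraction of municipalities have every
  registration deferred to the next "upload week" (week index ≡ 3 mod 4),
  the simplest week-grid emulation of monthly batch submission;
- *dropout*: with a per municipality-week probability, the whole week's
  volume is postponed past the delay horizon and arrives `D+1 .. D+16`
  weeks after the encounter — a missed upload amended within the registry's
  four-month window;
- three named profiles (`quality_profile()`): `prompt` (all mass within 2
  weeks, no dropout), `monthly` (batched uploads), `poor` (70% of volume
  delayed beyond 2 weeks, 25% dropout). No empirical delay distribution is
  available for the emulated registry, so the profiles are plausible
  stand-ins spanning the quality spectrum, not calibrated estimates.

**Reproducibility.** One master seed; each municipality's truth and
registration draws come from substreams keyed by a hash of its id, so adding
municipalities never reshuffles existing ones, and identical configs give
byte-identical outputs. Because profiles differ only in registration
parameters, runs that share a seed and municipality ids share the *same*
true incidence — which is what makes paired quality comparisons clean.

**What the generator does not emulate:** individual-level records,
diagnostic coding, age/sex structure, spatial correlation between
municipalities, or calendar effects beyond a single sinusoid. Passing tests
therefore demonstrate correctness of the *method* under controlled
divergence between views, not performance on any real registry.

## What the pipeline reports

```{r, eval = FALSE}
res <- run_pipeline(profile = "mixed", n_municipalities = 60,
                    n_weeks = 23, seed = 2024)
dplyr::filter(res$concordance, dimension == "suitable")
res$weekly_suitable$median
```

`run_pipeline()` chains simulate → views → DQI → detection → concordance and
returns every intermediate table plus a manifest (configs, seed, row counts
per stage); with `out_dir` set it writes each stage as CSV plus
`report.json`/`manifest.json`, and two runs with the same config are
identical except for timestamps.

## Simulation sizes used by the tests

The packaged checks run at desk scale, chosen once: the perfect-quality
limit at 50 municipalities × 23 weeks; the C2 oracle comparison on 1,000
random Poisson series of length 23; the delay-mass ordering (timely mass
0.3/0.6/0.9) on 20 paired seeds of 40 municipalities × 30 weeks; and the
suitable-vs-unsuitable stratum separation on 20 seeds of a 30+30
prompt/poor split × 30 weeks. At these sizes the qualitative properties —
ordering, separation, limits — are stable across seeds; absolute concordance
percentages are *not* comparable to national-scale registry analyses (5,570
municipalities, far larger per-municipality volumes), and the package makes
no claim that they are.

## Known limitations

- Vintage-mode detection recomputes a snapshot per evaluation week; at very
  large municipality counts a dedicated incremental implementation would be
  preferable.
- The C2 detector is the only detector provided (no C1/C3, Farrington, or
  nowcasting); concordance is the only warning-quality metric (no lead-time
  or ROC analysis).
- Real-time under-registration suppresses the evaluated week's count more
  than the baseline's, so vintage-mode C2 is conservative: real-time
  warnings are fewer, and `vs_realtime` concordance tends to be high while
  `vs_backfilled` concordance tracks data quality. That asymmetry is a
  finding about the design, not an artifact.
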
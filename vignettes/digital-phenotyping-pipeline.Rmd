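---
title: "Deriving and comparing digital-phenotype features from smartphone and wearable event streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and comparing digital-phenotype features from smartphone and wearable event streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digiphen)
```

## The problem

Remote-monitoring studies of attention-deficit/hyperactivity disorder (ADHD)
collect continuous, passive behavioural signals from a participant's
smartphone and wearable over weeks: when the phone was unlocked and locked,
which apps produced events, ambient light at the phone's sensor, minute-level
step counts, sleep intervals, and the timestamps around remotely pushed
symptom questionnaires. The hypothesis is that lapses of attention,
restlessness, and difficulty completing tasks leave measurable traces in
these streams — for example in how long it takes to open the phone after a
social or communication app notification.

`digiphen` implements the full analysis path for a two-group (ADHD versus
comparison) cohort: typed readers for the raw streams, sessionization of the
phone status log, derivation of ten behavioural features, outlier handling
with the IQR proximity rule, and group comparison with linear mixed models
(LMMs) and a t test, including a variance-component effect size. Because raw
streams from real cohorts are rarely shareable, the package also contains a
synthetic cohort generator whose derived features are moment-matched to
configurable group targets; the generator is first-class, tested code and the
basis of the package's calibration suite.

## Data model

Six stream kinds are supported (`stream_kinds()`), each a long-format table
keyed by participant and time, exchangeable as header-carrying CSV or
JSON-lines. Timestamps are epoch seconds (UTC); calendar days are defined by
a fixed per-cohort UTC offset (`utc_offset`, default 0), so daily aggregates
are reproducible and independent of the host's time zone. App package names
map to `SOCIAL` / `COMMUNICATION` / `OTHER_CATEGORY` through a static,
versionable two-column map rather than a live app-store lookup, keeping runs
hermetic; unmapped packages default to `OTHER_CATEGORY`.

## Sessions

An *active phone use session* spans from a device unlock (`UNLOCKED`) to the
next standby or shutdown. The paper-level definition leaves corner cases
open; `derive_sessions()` fixes them as follows, each the conservative
choice for duration-derived features:

* `SHUTDOWN` closes an open session (powering off ends active use);
  `BOOTED` never opens one.
* consecutive `UNLOCKED` events without an intervening terminator extend the
  same session — duplicate events occur in real logs;
* a trailing `UNLOCKED` with no terminator is dropped, not truncated to the
  end of the stream, because its true duration is unknown and truncation
  would bias durations downward; a counter of dropped opens is kept;
* zero-length spans are discarded.

Sessions are half-open `[start, end)` and pairwise disjoint by construction.

## Notification response latencies

A notification from a social or communication app appears in the app-event
stream as an `OTHER` event (followed by a `FOREGROUND`/`INTERACTION` event if
the user interacts with it). The behavioural quantity is the time until the
participant next *unlocks* the phone, so the matcher pairs each notification
with the first `UNLOCKED` event strictly after it. Decisions the source
material leaves open, all config-exposed:

* notifications delivered during a wearable-indicated sleep interval are
  excluded before matching (the participant almost certainly never saw
  them); intervals are half-open, and the operation is idempotent;
* several pending notifications may share one unlock, each with its own
  latency — no collapsing rule is imposed;
* a notification arriving during an ongoing session defaults to the latency
  to the *next* unlock (`during_session_policy = "next_unlock"`, with
  `"zero"` and `"drop"` available);
* latencies above a cap (default 24 h) are dropped and counted, so that
  never-seen notifications do not dominate daily SDs.

Daily aggregation keeps participant-days with at least `min_n = 2`
responses, so the daily sample SD (n − 1 denominator) always exists.

## The ten features

`feature_info()` lists the ten features with units and comparison method.
Features 1–4 come from questionnaire notification/start/finish timestamps:
the per-questionnaire response latency in hours (feature 1, a repeated
measure), its per-participant SD pooled across waves (feature 2, the single
non-temporal aggregate, compared with a t test), and the mean and SD of the
finish-to-next-start gaps within each assessment wave (features 3–4, one
observation per participant-wave; ordering within a wave follows
`started_at`, and negative gaps from overlapping completions are clipped to
zero with a warning). Questionnaires unanswered within their availability
window (default 72 h, i.e. 3 days) contribute no latency observation.

Features 5–6 are the daily mean and SD of the social/communication
notification latencies. Features 7–9 are session-level: the sample SD of
in-session illuminance (sessions with fewer than 2 readings are skipped),
the sum of in-session step counts (records attributed whole by timestamp
containment — the wearable already aggregates to the minute, so pro-rating
would be spurious), and the session duration. Feature 10 counts newly
appearing app packages per day: a package is "new" on the first local day it
ever appears, after a one-day burn-in that absorbs pre-installed apps, and
days with zero new apps are included as zeros (this choice lowers the mean
relative to dropping them; it is the natural reading of a daily count).

## Outlier handling

The IQR proximity rule computes `LL = Q1 − 1.5·IQR` and `UL = Q3 + 1.5·IQR`
per feature on the pooled values of both groups and removes values outside
the closed interval `[LL, UL]` (a per-group variant is config-selectable).
Percentiles use linear interpolation between order statistics
(`quantile()` type 7), fixed so limits are reproducible. With fixed limits
the removal is idempotent; recomputing limits on the retained values may
remove more, which the package deliberately does not do. A sensitivity
analysis re-runs the statistics after excluding the two participants with
the highest mean ambient-light SD.

One consequence worth stating plainly: on right-skewed features the rule
removes mass from the upper tail, so post-removal means sit noticeably below
the means of the underlying distributions (for heavily skewed features such
as the ambient-light SD the shift can exceed half the mean). The package's
calibration suite therefore checks generator-target recovery on the raw
derived observations, before the outlier stage, and treats the outlier rule
as a data-cleaning step whose effect is reported in the audit table rather
than folded into the recovery targets.

## Group comparison

Repeated features are compared with `value ~ group + (1 | participant_id)`
fitted by REML; the per-participant random intercept absorbs the
non-independence of repeated measures. The reported standard score is the
Wald statistic of the group term, coded comparison-minus-ADHD (ADHD is the
reference level), so a feature on which the ADHD group is higher gets a
negative score; p values use Satterthwaite degrees of freedom. The
mixed-model effect size is the group mean difference divided by the square
root of the summed variance components

d = |Δ| / √(var_intercept_participant + var_intercept_item +
var_slope_participant + var_slope_item + var_residual),

with components read off the fitted model. This study design has no crossed
item factor and no random slopes by default, so those components are zero; a
config flag adds a per-participant random slope on the day index. Effect
sizes are reported as magnitudes. The aggregated feature 2 uses a two-sided
pooled-variance t test with Cohen's d. No multiple-testing correction is
applied — the features are exploratory and correlated, and the report says
so.

Three modelling edge cases are handled explicitly. A *singular* fit (a
variance component estimated at zero) is flagged and warned about, but its
fixed-effect statistics are retained: a zero variance estimate is a
legitimate boundary estimate, and discarding the test there would silently
censor exactly the cases that arise when repeated measures happen to be
uncorrelated. A model that cannot be fitted at all falls back to the
descriptive comparison with `NA` statistics, flagged in the result. A
constant response yields the degenerate null comparison (difference 0,
d = 0, p = 1).

The day-by-group interaction model `value ~ group * day +
(1 | participant_id)` is available for the questionnaire-timing features;
under the coding above a negative interaction coefficient means the daily
increase is smaller in the comparison group.

Estimator choices left open by the source material: REML (the usual default
for variance components), covariates limited to group (plus day terms in the
interaction model), and observation-level descriptive means and SDs (a
per-participant aggregation mode is config-selectable).

## The synthetic cohort generator

`generate_cohort()` emulates a two-group cohort — by default 20 ADHD and 20
comparison participants, 10 weeks of 24/7 streams, enrolment on one date —
whose derived features are moment-matched to per-feature group targets
(`default_feature_targets()`, the published group summaries of the cohort
the package emulates). Design, in order of what a derived-feature pipeline
will see:

* **Questionnaires.** Three waves at 20%, 60% and 100% of the study span,
  five questionnaires each, pushed at 10:00 local. Each questionnaire's
  start latency and each finish-to-next-start gap are drawn directly from
  the feature-1 and feature-3 targets (moment-matched gamma: positive and
  right-skewed, well defined even when the SD exceeds the mean), and the
  notification times are solved backwards from the drawn values, so both
  feature families are controlled exactly. Draws beyond the 72 h window
  leave the questionnaire unstarted. A configurable group-specific day
  slope (hours/day, default +0.02 for ADHD) is added to the latency mean,
  centred on the mid-study day so the marginal group mean stays on target —
  this gives the interaction analysis a recoverable signal without moving
  the recovery targets.
* **Notifications and sessions.** Each day's notifications drip in through
  the morning and are all answered at the day's first unlock in the early
  afternoon; each arrival is placed at (unlock − latency), so the pipeline
  recovers each latency exactly, and no scheduled notification ever falls
  into a sleep interval. The day's latencies are constructed with their
  sample mean equal to a draw from the daily-mean target (feature 5) and
  their spread from the daily-SD target (feature 6); the recovered daily
  means are therefore unbiased for the target by construction. This was a
  deliberate trade: a naive serial schedule (notification, latency,
  session, repeat) couples the number of retained notifications per day to
  the day's own draws, and the equal-weighted average of daily means then
  acquires an inspection bias of several percent. The shared-unlock layout
  removes that bias at the cost of a stylised usage pattern; what it does
  *not* emulate is notification answering spread across the whole day.
  The remaining sessions (12 per day in total by default) run serially
  through the afternoon and evening with durations from the feature-9
  target; sessions that would start after 23:00 are dropped, a selection
  that never involves the session's own draws.
* **Light and steps.** Each session carries a two-level illuminance trace
  (as when moving between differently lit places) whose sample SD equals a
  per-session draw from the feature-7 target exactly, plus sparse ambient
  readings outside sessions; per-session step totals are drawn from the
  feature-8 target and spread multinomially over minute records inside the
  session, with occasional out-of-session walking records.
* **Sleep and night events.** One jittered nightly sleep interval
  (23:00–07:00); about every other night one notification is delivered
  mid-sleep, which the pipeline must exclude; a weekly night-time
  shutdown/boot pair exercises the session machinery's terminator handling.
* **New apps.** A Poisson count of novel package names per day (matched to
  the feature-10 mean), after a first-day burn-in during which all base
  packages appear.
* **Heterogeneity.** By default (`icc = 0`) observations are drawn from the
  marginal target distributions — the printed mean and SD are matched
  directly, which keeps recovery standard errors minimal. With `icc > 0`
  each participant receives a latent mean carrying `sqrt(icc)` of the
  target SD, with the remaining variance within participants; the marginal
  moments are preserved exactly (the variance decomposition is additive),
  while repeated measures now correlate within participants — the regime
  the mixed model assumes. The calibration suite uses `icc = 0.3` for the
  null-calibration study below, a mid-range value for repeated behavioural
  measures.

Generation is deterministic given `seed`; identical seeds give
byte-identical cohorts. Features 2 and 4 are *emergent* — they are SDs of
features 1 and 3 — and the generator makes no attempt to hit their printed
values independently; with iid draws the recovered feature-2 mean sits near
the feature-1 SD. The published feature-2 value exceeding the published
feature-1 SD (and likewise for feature 4) cannot be produced by any
within-participant iid mechanism, so those two rows are carried in the
target table for completeness but are not recovery targets. The recovered
feature-6 mean runs some 20% below its target: the per-day spread draw is
capped at 2.5 times the day's mean (unbounded spreads around a small daily
mean are not realisable with non-negative latencies) and scaled to an exact
sample mean; this is a documented limitation, not a calibration goal.

What passing the calibration suite shows — and what it does not: recovery of
the configured marginal moments demonstrates that sessionization, interval
joins, sleep exclusion, unlock matching and the aggregations are correct and
unbiased; it does not show that real cohorts look like the generator (real
streams have missing data, device swaps, time-zone changes, circadian
structure and app ecosystems the generator deliberately omits).

## Numerical and calibration choices

Problem sizes used by the packaged checks, chosen to give tight Monte Carlo
error at interactive runtimes: one full-scale cohort (20+20, 10 weeks) for
parameter recovery, judged at three standard errors of each recovered
sample; 1000 reduced null cohorts (10+10, 2 weeks, identical group targets,
`icc = 0.3`) for the size of the LMM group test, expected in 5% ± 1.5%;
1000 random inputs per statistical primitive against brute-force oracles at
1e-10 relative tolerance; 100 reduced simulations for the sign of the
day-by-group interaction under an injected ADHD slope of 0.1 h/day —
detectably larger than the cosmetic default drift, as a sign-recovery test
should be. Null calibration is assessed with participant heterogeneity
present (`icc = 0.3`) because at `icc = 0` the random-intercept variance
lies on the boundary of the parameter space, where Wald-type tests are
well known to be conservative (the measured rejection rate there is near
2.5%); the criterion is about the test's calibration in its intended
regime, not about boundary pathology.

On-disk numerics: numeric fields are written with up to 17 significant
digits, so write-then-read reproduces doubles bit-for-bit and the round-trip
identity tests are exact.

## Known limitations

* The generator's usage pattern is stylised (morning notification queue,
  one response unlock, afternoon sessions); it calibrates the pipeline, not
  a behavioural model of phone use.
* Features 2, 4 and 6 are emergent rather than injected (above).
* The zero-inflated new-apps feature is modelled with the same LMM as the
  other features, mirroring the analysis it implements; a count-model
  alternative is deliberately out of scope.
* Ambient light is not calibrated across devices, and sleep intervals are
  consumed as given — the wearable's sleep-staging algorithm is out of
  scope.
* Time-zone handling is a single fixed offset per cohort; travelling
  participants would need per-participant offsets.

## A worked example

```{r, eval = FALSE}
library(digiphen)

cfg <- cohort_config(n_per_group = 4, weeks = 2, seed = 11)
res <- run_pipeline(cfg, output_dir = "pipeline_out")
res$report
res$sensitivity_report
```

The report prints one row per feature with group means (SD), the p value,
the standard score, the effect size and the comparison method, and the
sensitivity report repeats the analysis without the two
highest-ambient-light-SD participants.
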
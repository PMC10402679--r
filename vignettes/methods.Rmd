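---
title: "Risk-matrix determination of QC frequencies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-matrix determination of QC frequencies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmqc)
```

## The estimation problem

Routine machine QC trades risk against effort: test an item too rarely and
a failure can silently degrade treatments; test it too often and physicist
time is wasted. `rmqc` treats each *(QC item, test interval)* pair as a
failure mode and scores it semi-quantitatively. The analysis chain is

1. failure quantities from records — severity from dose perturbations,
   occurrence from out-of-tolerance time, detection from undetected-failure
   time;
2. quantities → integer ranks 1–10 through fixed threshold scales;
3. (S, O) rank pairs → low/medium/high via the 10×10 risk matrix;
4. per item, a scan over the interval grid → the recommended frequency;
5. schedule comparison via E = O/D.

The method's central assumption is that risk is adequately summarized by
the (S, O) pair: detection enters scheduling only indirectly, through the
comparison metric. A second structural assumption is that severity grows
with the test interval (a sustained error harms more fractions), which is
what makes the first-medium scan well-defined on most real data.

## Ranking scales

`rank_tables()` holds four scales of nine strictly increasing upper
bounds; rank *r* ≤ 9 is the smallest whose bound covers the quantity, and
rank 10 is anything beyond the ninth bound. Bounds are inclusive: a
quantity exactly at a bound takes the lower rank, consistent with
tolerances being stated as limits. The severity scales are in percentage
points of PTV coverage change and cGy of maximum-cord-dose change; the
occurrence and detection scales are percentages of observation time.

One deliberate asymmetry: an item whose record contains no failure gets
occurrence rank 2, never 1. Rank 1 on the occurrence scale asserts an
out-of-tolerance fraction below 0.01%, about one day in thirty working
years — more than a finite clean record can support.

## Estimators

**Occurrence.** The quantity is (days attributable to an out-of-tolerance
state) / (period days) × 100. The record is a point process, so a
state-holding rule is needed: an out-of-tolerance measurement marks the
item failed from its date until the next in-tolerance measurement or the
item's repair, whichever comes first; each calendar day counts once even
when marked by several measurements. The rule is deliberately one-sided —
it never back-fills days before the first failing measurement — so the
estimate is conservative with sparse testing.

**Detection.** A failure flagged by the QC test itself was detected when
detectable and contributes nothing. A failure found otherwise contributes
half the time between the last QC test that did not report it and its
discovery: the true onset is only bracketed by that gap, and half the gap
is its expected position under a uniform prior. The denominator is the
same observation period as for occurrence, which keeps O and D
commensurable in E = O/D.

**Severity.** Per patient, the PTV and cord quantities are ranked on their
own scales and combined; the default combination is the maximum of the two
ranks, a worst-case choice made because no canonical combination exists
for a two-criterion severity scale. Pooling over the cohort defaults to
the *mean of per-patient ranks*, because observed mean severity indices
are fractional (1.200, 2.950, …), which a rank-of-mean-quantities pooling
cannot produce; `pooling = "rank_of_means"` is retained since the
narrative definition of the quantity ("mean dose variation") reads that
way. Both are exposed because the choice is genuinely open.

## The risk matrix and the interval scan

`classify_risk()` applies the band rules in a fixed precedence: S = 1
first, then the O = 1 column (low, except medium at S ≥ 9 — very severe
failure modes deserve mitigation even if never observed), then the O+S
bands (S 2–5: medium at 9–10, high at 11–15; S 6–10: medium at 9–11, high
at 12–20). This precedence is the only ordering consistent with both the
"S = 1 or O = 1 is low" clause and the S ≥ 9 amendment. The resulting
100-cell matrix partitions into 32 low, 19 medium, and 49 high cells and
is monotone non-decreasing in both ranks; the test suite checks it cell by
cell against an independently transcribed rule table.

`recommend_frequency()` scans a item's intervals from shortest to longest
and recommends the first medium cell. Two fallbacks cover traces the
primary rule does not: all-low traces recommend the longest tested
interval (all risk acceptable, take the least effort), and traces that
jump from low straight to high recommend the last interval before the
first high. A trace that is high already at the shortest interval is an
error — the item needs escalation beyond the tested grid, not a schedule.
Non-monotone traces (possible with noisy severity means) are scanned in
grid order with a warning rather than re-sorted, since re-sorting would
hide the anomaly.

Rounding fractional mean severity ranks to integers defaults to nearest,
half away from zero (`round_half_away()`), with floor and ceiling
available. On the reference per-interval severity means, nearest rounding
reproduces five of the six published recommendations; the isocenter-size
item is the known exception (its D14 mean of 6.556 rounds to 7, putting
O+S = 9 in the medium band, so the scan stops at D14 where the published
choice is D21). Floor rounding fixes that item but breaks the gantry item
(2.950 → 2 is low at D7). No single convention reproduces all six, so the
default stays nearest and the discrepancy is documented rather than
patched per item.

## The synthetic generator

`simulate_machine_log()` emulates the data-generating reality behind a QC
record set: failures arrive as a memoryless (daily-Bernoulli) process at a
configurable rate per working year; a failed parameter sits at a fixed
multiple of its tolerance until repaired; healthy days drift with Gaussian
noise clipped inside tolerance; QC tests run on a fixed working-day
interval and flag a true exceedance with configurable sensitivity; missed
failures are found by service after a configurable delay, and repairs
complete after a configurable lag. All days are working days (20 per
month, 240 per year), so the default 360-day period represents 1.5
calendar years. A missed test records a healthy-looking deviation — the
measurement failed to reveal the fault — which keeps tolerance flags
consistent with recorded deviations by construction.

Ground truth is kept by exhaustive day-by-day bookkeeping, separately
from the estimators: latent out-of-tolerance days (the true state),
observed out-of-tolerance days (what the records alone support, counted by
a brute-force day scan), the half-interval undetected durations
accumulated at discovery time, and latent undetected days. The pipeline
tests require the estimators to reproduce the observed quantities exactly
after a CSV round trip; the latent quantities are reported so the gap
between estimand and truth stays visible.

Default study conditions: six QC items with their institutional
tolerances; failure rate 2/3 per working year for the gantry-angle item
(one failure per 360-day period in expectation, matching an out-of-
tolerance fraction of 0.278% when failures are caught at once and repaired
next day) and zero for the others, which never failed over the reference
period; monthly testing (20 working days); detection sensitivity 1; repair
delay 1 day; service delay 6 days. The Monte-Carlo recovery test uses 200
seeded replicates of the 360-day period under daily QC, where the
estimator is fully observed, and checks the mean estimate against the
expected fraction within three Monte-Carlo standard errors.

`simulate_dose_metrics()` draws per-patient dose deviations around
`base_effect × (interval/shortest)^exponent` with lognormal unit-mean
patient variability. The interval-scaling law is an explicit stand-in: the
mechanism by which severity grows with interval is not modeled
mechanistically anywhere, so the generator names it as a parameter
(default exponent 0.75, CV 0.3, base effects calibrated so cohort mean
ranks rise from about 1 at daily testing to 8–9 at bimonthly) instead of
burying it. What the generator does **not** emulate: real plan dosimetry,
correlated multi-item failures, drifts that grow gradually rather than
step out of tolerance, seasonal workload, or measurement-device error
beyond the sensitivity parameter. Passing tests therefore demonstrate
estimator and rule correctness, not that any particular clinic's logs obey
these models.

## Numerical conventions and degenerate inputs

- Dates are ISO-8601; durations are whole-day date differences. Duty
  calendars (working days) are the generator's concern, not the
  estimators'.
- Tolerance boundaries are within tolerance; ranking bounds are inclusive
  upper limits.
- E is reported to two decimals, half away from zero (2/6 → 0.33,
  2/7 → 0.29).
- An empty or all-clean log yields occurrence rank 2 with quantity 0; an
  empty service record yields detection rank 1.
- A rounded severity rank outside 1–10 is clamped with a warning; O and D
  ranks outside 1–10 are errors.
- Readers reject unknown item ids, off-grid intervals, negative dose
  magnitudes, and out-of-order event dates, naming the offending row.

## Problem sizes

The test suite and the acceptance script run on desk-scale inputs chosen
to exercise every code path: 360-day single-item logs for the worked
examples, 60-day logs for the randomized oracle comparisons (20
replicates), 200 seeded 360-day simulations for the Monte-Carlo recovery
check, and ten-patient cohorts on the six-interval grid for the severity
pipeline. These sizes match the reference setting (1.5 working years, ten
patients, six items, six intervals) where a setting exists, and otherwise
were chosen once as realistic for a single-machine QC program.

## Limitations

The method inherits FMEA's subjectivities: the threshold scales are
conventions, the two severity criteria have no canonical combination, and
the half-interval detection assumption is an expectation argument, not an
observation. The recommendation uses S and O only, so two items with equal
(S, O) but very different detectability get the same interval. Occurrence
estimates from sparse records are lower bounds more than point estimates.
None of these are resolved here; they are surfaced as the configurable
knobs (`rounding`, `aggregation`, `pooling`, custom `tables`) so a clinic
can state its own policy explicitly.
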
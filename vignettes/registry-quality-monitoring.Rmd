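---
title: "Monitoring data quality in a maternal-newborn health registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring data quality in a maternal-newborn health registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regqc)
```

## The monitoring model

A population-based pregnancy registry follows every pregnancy in a set of
geographic clusters (each around 300–500 births a year) from consent
through delivery to a six-week postpartum visit. Four forms generate the
data: enrollment, delivery (one per pregnancy, covering miscarriages too),
per-infant birth outcomes, and the six-week follow-up. Quality control is
quantitative: a catalogue of indicators is recomputed monthly per cluster
and for the pooled site, each compared with an acceptable value, and an
edit report lists record-level findings for field resolution.

The indicators are deliberately simple — windowed proportions, ratios and
counts with transparent numerators and denominators — because their role is
diagnostic, not inferential. Three design ideas matter:

* **Completeness is measured against expectation.** A delivery outcome is
  "expected" once the estimated delivery date (EDD) plus a grace period has
  passed; a six-week outcome is "due" 42 days plus a grace period after
  delivery. Denominators are therefore built from *obligations*, not from
  whatever happened to be entered.
* **Consistency ratios proxy misclassification.** Stillbirths and early
  neonatal deaths (death on day of life < 7) occur at comparable rates in
  this setting, so the stillbirth:END ratio should sit between 0.5 and 2.0;
  a high value suggests early deaths recorded as stillbirths. Likewise
  early deaths should be the majority — 60–90 % — of all deaths by day 42.
  Unusual sex ratios (outside 0.80–1.30 males per female) suggest selective
  under-ascertainment.
* **Timeliness bounds accuracy.** Day gaps between event, form completion
  and data entry are checked against strict windows (e.g. delivery form
  completed < 28 days after delivery), since recall degrades with distance
  from the event.

## Windows, scopes and flags

Indicators are computed over an `analysis_window()`: a span of whole
calendar months ending at the report month, 6 months for rolling
indicators (the reporting convention), 12 for annual summaries. Events are
bucketed by their own calendar date — enrollment metrics by enrollment
date, outcome metrics by delivery date. Site-scope values always pool
numerators and denominators across clusters; they are never means of
cluster values, so a small cluster cannot drag the site figure.

Flagging semantics required a decision the printed protocol leaves
implicit. Acceptable values are printed with strict operators ("> 95 %",
"< 2.0"), yet achievement is described as *meeting* the value ("at least
95 %"). `regqc` therefore flags **inclusively at the bound** (95.0 is
acceptable against "> 95 %"), while the record-level day-gap rules inside
the process indicators keep their printed strict form (a 28-day gap fails
"less than 4 weeks"). Both choices are tested explicitly, including
one-ulp-past-the-bound cases.

Degenerate inputs resolve as follows: a zero denominator yields an `NA`
value flagged `insufficient_data`, never an error or an infinity. A zero
month inside a variability window (max/min of six monthly counts) makes
the factor undefined rather than infinite — the alarm for an empty month
belongs to the minimum-deliveries indicator, which reports a true zero as
`out_of_range`. A unit with *no delivery history at all* gets
`insufficient_data` on that indicator instead: absence of data is not a
zero month. The enrollment-pipeline indicator needs twelve months of
delivery history for its baseline and is `insufficient_data` without it.

Three readings of ambiguous catalogue rows are worth recording:

* The weight-recording latency row prints a **day** bound ("< 7 days"),
  not a percentage; its result is the *median* day gap from birth to
  weight measurement, flagged against 7 days, while the companion
  percent-within-7-days indicator carries the ≥ 95 % bound.
* The protocol prints two delivery-entry latency rows ("collection of
  delivery information → entry" and "completion of delivery form →
  entry"); the record model carries a single completion date, so both
  indicator ids are shipped and compute the same gap.
* The miscarriage row states a record-level rule (gestational age
  < 20 weeks *and* weight < 500 g) with no percentage; it is shipped as
  "proportion of assessable miscarriages consistent with the rule" with a
  bound of 100 %.

Two further conventions: "neonatal death" in the birth-weight
stratification means death by day 42, matching the registry's follow-up
horizon; and the sex ratio includes stillbirths with known sex, since they
are registered births (infants of unknown or ambiguous sex are excluded
from both numerator and denominator). Grace periods — 42 days past the EDD
before a delivery is overdue, 21 days past the six-week visit before
follow-up is overdue — are configurable defaults; the protocol does not
specify them.

## What the simulator emulates

`simulate_registry()` exists so every indicator, edit check and report can
be exercised — and its failure modes demonstrated — without access to any
real registry extract. It draws, per cluster:

* monthly birth counts from an inhomogeneous Poisson process, annual rate
  uniform in `births_per_cluster_year` (default 300–500), with a shared
  sinusoidal seasonal component (`seasonality_amplitude`, default 0.10 —
  mild seasonality of the kind marriage customs and agricultural calendars
  produce);
* per-infant outcomes: stillbirth, early (day 0–6) and late (day 7–42)
  neonatal death, miscarriage, twin pregnancy and infant sex from
  configured probabilities. The defaults (3 % stillbirth, 2.4 % early and
  0.8 % late neonatal death, 2 % miscarriage, 51.5 % male) are documented
  placeholders for a generic high-mortality setting chosen to sit
  comfortably inside the monitoring ranges (SB:END ≈ 1.29, END:6-week
  ≈ 0.75, sex ratio ≈ 1.06); they are not estimates for any particular
  site;
* timing: enrollment ~150 days (log-normal) before the EDD — women
  enrolled by roughly 20 weeks' gestation — and form/data-entry latencies
  log-normal with medians well inside the process windows (delivery form
  ~5 days, data entry ~7 days, weight measurement ~1.5 days, follow-up
  form ~45 days), so that a defect-free simulation is a *known-good
  baseline*: every site-scope indicator acceptable and zero edit items.
  Pregnancies due shortly after the simulated span appear as
  enrollment-only rows, giving the expected-deliveries indicator a
  realistic pipeline at the end of the span.

Quality problems are then injected *orthogonally* by `inject_defects()`:
eight independent per-record corruption knobs (weight loss or downgrade,
death misclassification, follow-up loss, entry delay, consent loss,
enrollment-at-delivery, delivery-field loss), each with a configured rate
and a complete change ledger. Every knob has a paired indicator that
degrades monotonically in its rate, which is what the test battery
verifies at rates 0 / 0.3 / 1.0, together with the analytic extremes at
saturation.

What the simulator does **not** emulate — and what passing tests therefore
do not establish about real data: demographic structure (maternal age,
parity, antenatal care), cluster heterogeneity in mortality, reporting
censoring at the extract date (forms entered after the extract date are
included, since entry latencies are short by construction), correlated or
adversarial data-quality failures, and true rates for any specific site.
Cluster-scope ratio indicators are intrinsically noisy at registry volumes
(an SB:END ratio over a six-month cluster window rests on a handful of
events), so occasional cluster-level out-of-range flags in a defect-free
simulation are expected sampling noise — in real monitoring exactly these
flags prompt review, not alarm. The known-good-baseline property is
therefore asserted at site scope, where pooled denominators make it hold
analytically.

## Edit checks

The shipped rule set mirrors a coordinating-center edit report: range
checks (gestational age outside 4–46 weeks, birth weight outside
200–6500 g — operational screening bounds, editable per site, not
physiologic claims), a skip check (bag-and-mask answered for a
miscarriage), cross-form checks (delivery without documented consent,
stillbirth carrying a day of death, miscarriage failing the
< 20 weeks / < 500 g rule) and missing-expected-form checks driven by the
EDD and delivery-date horizons (42 and 63 days). Severity defaults follow
the convention that missing-form and mortality-consistency findings are
critical — they feed the ≥ 80 % critical-edit-resolution indicator — while
single-field range violations are not. The engine is pure: identical
extracts yield byte-identical, stably ordered edit reports. Overdue-form
checks take an explicit `as_of` date, defaulting to the latest *event*
date in the extract (entry dates may postdate the extract period, and
pipeline EDDs lie in the future by design).

## Reports and re-keying

`build_report()` assembles, for one cluster or the pooled site, the full
battery for the report month, a trailing six-month moving-average series
per indicator (each point recomputed over the window ending at that
month, so a constant series reproduces the constant), flag and edit
summaries, and the trend tables reviewed in site meetings: yearly delivery
outcome, monthly births per cluster, the distribution of cluster SB:END
ratios across the < 0.5 / 0.5–2.0 / > 2.0 categories, the
measured/estimated/missing birth-weight breakdown, and monthly
delivery-form timeliness. Reports export as bit-stable CSVs. A monthly
cadence is the default; a quarterly roll-up is a span argument away, and
site values stay pooled either way. `rekey_sample()` draws the seeded
per-cluster 5 % sample of forms entered in a month (ceiling rule, so one
entered form still yields one sampled id) for double data entry; the 5 %
protocol floor is enforced.

## Verification sizes and limitations

The test battery uses problem sizes chosen to keep the full suite around a
minute while leaving multi-sigma margins: 50 randomized fixtures of ≤ 200
records for oracle equivalence against an independently written
brute-force recomputation (tolerance 1e-9); 20 clusters × 36 months for
parameter recovery of an SB:END ratio placed analytically at 1.25
(accepted within 3 Monte-Carlo standard errors); 10 clusters × 24 months
for the known-good baseline and the defect-flip matrix. Defect rates in
the flip tests (0.2–0.8 per knob) were chosen analytically so the paired
indicator lands many standard deviations beyond its bound, never at it.

Known limitations: the toolkit evaluates *internal* consistency and
timeliness only — it cannot detect completeness failures invisible to the
registry itself (births never identified), which in practice require
household surveys and facility-record liaison; double data entry is
supported only up to the sampling list (no comparison engine); and the
indicator catalogue, while override-able in its bounds, has a fixed set of
indicator identities by design, so that longitudinal results remain
comparable across sites and time.
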
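# regqc

Data-quality indicators and monitoring reports for population-based
maternal–newborn health registries.

## The problem

Prospective population-based pregnancy registries in low-resource settings
are often the only reliable source of stillbirth, neonatal-mortality and
maternal-outcome statistics for their catchment areas. Their value depends
entirely on the completeness, accuracy and timeliness of data collected by
field staff across many geographic clusters — and those properties have to
be *monitored*, continuously, at the cluster level, or quality problems
(missed births, misclassified deaths, stale forms) go unnoticed until the
data are unusable.

`regqc` implements the quantitative monitoring battery used for this kind
of registry as a reusable toolkit, aimed at data-coordinating-center
statisticians and site data managers. It covers five indicator families,
each flagged against a catalogue of acceptable values:

| family | examples | typical bound |
|---|---|---|
| enrollment | consent documentation; month-to-month enrollment variability factor (max/min over a trailing 6-month window) | ≥ 95 %; ≤ 2.0 |
| pregnancy outcome | expected delivery outcomes obtained; 6-week follow-up obtained; sex ratio (M/F); minimum 25 deliveries/cluster/month | ≥ 95 %; 0.80–1.30 |
| mortality | stillbirth : early-neonatal-death ratio (SB/END, END = death at day < 7); END : 6-week-death ratio | 0.50–2.0; 0.60–0.90 |
| key variables | measured vs estimated vs missing birth weight by outcome class; conjunctive field completeness | ≥ 75–99 % |
| process | day gaps between event, form completion and data entry (e.g. delivery → form < 28 days); critical-edit resolution | ≥ 80–90 % |

Mortality *ratio* indicators deserve a word: they are not epidemiology but
consistency checks. In a well-run registry stillbirths and early neonatal
deaths occur at broadly comparable rates, so a cluster whose SB/END ratio
drifts far above 2 is most plausibly misclassifying early deaths as
stillbirths (or missing live births that die), and the indicator points the
field team at exactly that question.

The package also provides:

* a **record model** with validating readers/writers for the five
  delimited registry tables (enrollment, delivery, births, follow-up,
  edits), with row-level diagnostics instead of silent drops;
* an **edit-check engine** (range, skip, cross-form and
  missing-expected-form rules) emulating a coordinating center's edit
  reports, plus resolution tracking;
* a seeded **registry simulator** (300–500 births/cluster/year, seasonal
  birth process, configurable mortality probabilities and form/entry
  latency distributions) with an orthogonal **defect-injection layer**
  (8 independent corruption knobs with a full change ledger), so every
  indicator and check can be exercised end-to-end without any real data;
* **monitoring reports** per cluster or pooled site (indicator battery,
  trailing moving averages, flag and edit summaries, figure-style trend
  tables) exported as bit-stable CSV, and the monthly 5 % **re-keying
  sample** for double data entry.

## Worked example

```r
library(regqc)

reg <- simulate_registry(simulation_config(n_clusters = 4, months = 18,
                                           seed = 42))
reg
#> <registry_tables>
#>   enrollments    3536 rows
#>   deliveries     2843 rows
#>   births         2876 rows
#>   followups      2843 rows
#>   edits             0 rows

m <- compute_metrics(reg, "2021-06", scope = "site")
m[m$metric_id %in% c("delivery_outcome", "sex_ratio", "sb_end_ratio"),
  c("metric_id", "numerator", "denominator", "value", "flag")]
#>          metric_id numerator denominator    value       flag
#>   delivery_outcome       724         724 100.0000 acceptable
#>          sex_ratio       487         430   1.1326 acceptable
#>       sb_end_ratio        23          26   0.8846 acceptable
```

Over the six months ending 2021-06 this site recorded a delivery outcome
for all 724 pregnancies whose EDD (plus a 42-day grace period) had passed,
a sex ratio of 487 males to 430 females (1.13, inside 0.80–1.30), and 23
stillbirths against 26 early neonatal deaths (ratio 0.88, inside 0.50–2.0).
A defect-free simulation is a known-good baseline: every indicator is
acceptable and `run_checks(reg)` returns zero edit items.

Quality problems surface as flags. Dropping 40 % of birth weights:

```r
bad <- inject_defects(reg, defect_config(drop_birth_weight = 0.4), seed = 9)
build_report(bad, "2021-06", scope = "site")
#> <monitoring_report> site site, month 2021-06
#>   indicators: 29 (22 acceptable, 6 out of range, 1 insufficient)
#>   out of range: bw_measured_live, bw_any_live, bw_measured_neonatal_death,
#>                 bw_any_neonatal_death, bw_measured_stillbirth, bw_any_stillbirth
```

exactly the six birth-weight capture indicators flip, and nothing else.
`export_report()` writes the report as documented CSVs;
`inst/cli/regqc.R` exposes `simulate` / `inject` / `metrics` / `edits` /
`report` / `rekey` verbs for shell use.

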
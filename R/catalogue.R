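#' The shipped indicator catalogue
#'
#' One definition per monitored indicator: its category, the acceptable value
#' printed in the registry's monitoring protocol, and the comparison semantics
#' used for flagging. Bounds are flagged *inclusively* (a value exactly at the
#' bound is acceptable); the strict operators printed in the protocol apply to
#' the record-level day-gap rules inside the process indicators, not to the
#' aggregate flag (see the methods vignette).
#'
#' Units: `proportion_pct` values run 0-100; `ratio` values are plain ratios;
#' `count` is an event count; `days` is a whole-day latency.
#'
#' @return A tibble with columns `metric_id`, `category`, `description`,
#'   `lower_bound`, `upper_bound`, `bound_semantics`, `units`.
#' @export
metric_catalogue <- function() {
  tribble <- tibble::tribble
  tribble(
    ~metric_id, ~category, ~description, ~lower_bound, ~upper_bound,
      ~bound_semantics, ~units,
    # --- enrollment -------------------------------------------------------
    "consent_rate", "enrollment",
      "Proportion of enrolled subjects with consent obtained",
      95, NA, "at_least", "proportion_pct",
    "enroll_variability", "enrollment",
      "Month-to-month enrollment variability factor over the past 6 months",
      NA, 2.0, "at_most", "ratio",
    # --- pregnancy outcome ------------------------------------------------
    "delivery_outcome", "pregnancy_outcome",
      "Proportion of expected delivery outcomes obtained",
      95, NA, "at_least", "proportion_pct",
    "followup_outcome", "pregnancy_outcome",
      "Proportion of deliveries with a 6-week neonatal outcome obtained",
      95, NA, "at_least", "proportion_pct",
    "sex_ratio", "pregnancy_outcome",
      "Male:female ratio among births with known sex",
      0.80, 1.30, "within_range", "ratio",
    "birth_variability", "pregnancy_outcome",
      "Month-to-month birth variability factor over the past 6 months",
      NA, 2.0, "at_most", "ratio",
    "expected_deliveries", "pregnancy_outcome",
      "Expected deliveries (next 6 months) vs average monthly deliveries",
      70, NA, "at_least", "proportion_pct",
    "min_deliveries", "pregnancy_outcome",
      "Minimum number of deliveries per month per cluster",
      25, NA, "exact_minimum", "count",
    # --- mortality --------------------------------------------------------
    "sb_end_ratio", "mortality",
      "Ratio of stillbirths to early neonatal deaths",
      0.50, 2.0, "within_range", "ratio",
    "end_sixwk_ratio", "mortality",
      "Ratio of early neonatal deaths to 6-week neonatal deaths",
      0.60, 0.90, "within_range", "ratio",
    "miscarriage_consistency", "mortality",
      "Miscarriages with gestational age <20 weeks and weight <500 g",
      100, NA, "at_least", "proportion_pct",
    # --- key variables ----------------------------------------------------
    "bw_measured_live", "key_variable",
      "Measured birth weight: live births",
      95, NA, "at_least", "proportion_pct",
    "bw_measured_neonatal_death", "key_variable",
      "Measured birth weight: neonatal deaths",
      90, NA, "at_least", "proportion_pct",
    "bw_measured_stillbirth", "key_variable",
      "Measured birth weight: stillbirths",
      75, NA, "at_least", "proportion_pct",
    "bw_any_live", "key_variable",
      "Any birth weight recorded: live births",
      99, NA, "at_least", "proportion_pct",
    "bw_any_neonatal_death", "key_variable",
      "Any birth weight recorded: neonatal deaths",
      95, NA, "at_least", "proportion_pct",
    "bw_any_stillbirth", "key_variable",
      "Any birth weight recorded: stillbirths",
      95, NA, "at_least", "proportion_pct",
    "maternal_anthro_complete", "key_variable",
      "Enrolled subjects with maternal height, weight and timing recorded",
      95, NA, "at_least", "proportion_pct",
    "delivery_fields_complete", "key_variable",
      paste("Deliveries with attendant, location, mode, bag and mask use,",
            "and gestational age recorded"),
      99, NA, "at_least", "proportion_pct",
    "bw_within_7d", "key_variable",
      "Deliveries with birth weight collected within 7 days of birth",
      95, NA, "at_least", "proportion_pct",
    # --- process ----------------------------------------------------------
    "bw_recording_latency", "process",
      "Days between birth and (measured or estimated) birth weight recorded",
      NA, 7, "at_most", "days",
    "enroll_entry_6wk", "process",
      "Enrollment to data entry under 6 weeks",
      90, NA, "at_least", "proportion_pct",
    "enroll_edd_4wk", "process",
      "Enrollment at least 4 weeks before the estimated delivery date",
      70, NA, "at_least", "proportion_pct",
    "delivery_collection_entry_6wk", "process",
      "Collection of delivery information to data entry under 6 weeks",
      90, NA, "at_least", "proportion_pct",
    "delivery_form_4wk", "process",
      "Delivery to completion of delivery form under 4 weeks",
      90, NA, "at_least", "proportion_pct",
    "delivery_form_entry_6wk", "process",
      "Completion of delivery form to data entry under 6 weeks",
      90, NA, "at_least", "proportion_pct",
    "followup_form_5_9wk", "process",
      "Delivery to completion of follow-up form between 5 and 9 weeks",
      80, NA, "at_least", "proportion_pct",
    "followup_entry_6wk", "process",
      "Completion of follow-up form to data entry under 6 weeks",
      90, NA, "at_least", "proportion_pct",
    "critical_edits", "process",
      "Proportion of critical edits addressed",
      80, NA, "at_least", "proportion_pct"
  )
}

#' Load the indicator catalogue, optionally overriding bounds
#'
#' With no argument, returns the shipped defaults ([metric_catalogue()]).
#' A YAML override file may adjust `lower_bound` / `upper_bound` of existing
#' indicators but cannot add or remove indicator identities:
#'
#' ```yaml
#' delivery_outcome: {lower_bound: 90}
#' sex_ratio: {lower_bound: 0.85, upper_bound: 1.25}
#' ```
#'
#' @param config_path Optional path to a YAML override file.
#' @return The catalogue tibble (see [metric_catalogue()]).
#' @export
load_metric_catalogue <- function(config_path = NULL) {
  cat <- metric_catalogue()
  if (is.null(config_path)) return(cat)
  if (!file.exists(config_path))
    abort_regqc(paste("file not found:", config_path), "regqc_missing_file")
  ov <- yaml::read_yaml(config_path)
  if (!is.list(ov))
    abort_regqc("malformed catalogue override file", "regqc_bad_config")
  for (id in names(ov)) {
    i <- match(id, cat$metric_id)
    if (is.na(i))
      abort_regqc(paste("override references unknown metric_id:", id),
                  "regqc_unknown_metric")
    entry <- ov[[id]]
    bad <- setdiff(names(entry), c("lower_bound", "upper_bound"))
    if (!is.list(entry) || length(bad) > 0)
      abort_regqc(sprintf("override for '%s' may only set lower_bound/upper_bound",
                          id), "regqc_bad_config")
    for (fld in names(entry)) cat[[fld]][i] <- as.numeric(entry[[fld]])
    if (cat$bound_semantics[i] == "within_range" &&
        (is.na(cat$lower_bound[i]) || is.na(cat$upper_bound[i]) ||
         cat$lower_bound[i] > cat$upper_bound[i]))
      abort_regqc(sprintf("override for '%s' leaves an invalid range", id),
                  "regqc_bad_config")
  }
  cat
}
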
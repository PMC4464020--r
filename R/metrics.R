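#' Indicator computation
#'
#' Every indicator is computed from a [registry_tables()] extract over an
#' [analysis_window()], and returned as a one-row (or few-row) *metric result*
#' tibble with full numerator/denominator transparency:
#' `metric_id, category, scope, scope_id, window_start, window_end_month,
#' numerator, denominator, value, flag`.
#'
#' Events are bucketed into calendar months by their own date: enrollment
#' metrics by `enrollment_date`, outcome metrics by `delivery_date`. Values of
#' proportion indicators are percentages in \[0, 100\]. A denominator of zero
#' yields an `NA` value and an `insufficient_data` flag.
#'
#' @name indicator-computation
NULL

filter_cluster <- function(reg, cluster_id) {
  en <- reg$enrollments[reg$enrollments$cluster_id == cluster_id, ]
  ids <- en$study_id
  out <- list(
    enrollments = en,
    deliveries = reg$deliveries[reg$deliveries$study_id %in% ids, ],
    births = reg$births[reg$births$study_id %in% ids, ],
    followups = reg$followups[reg$followups$study_id %in% ids, ],
    edits = reg$edits[reg$edits$study_id %in% ids, ]
  )
  class(out) <- "registry_tables"
  out
}

# births joined to their delivery date (and cluster, via the delivery row)
births_dated <- function(reg) {
  dplyr::left_join(
    reg$births,
    reg$deliveries[, c("study_id", "cluster_id", "delivery_date")],
    by = "study_id"
  )
}

pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
ratio_of <- function(num, den) if (den > 0) num / den else NA_real_

#' Consent rate
#'
#' Percent of subjects enrolled during the window with consent documented.
#' @param reg A [registry_tables()] extract (already restricted to a cluster
#'   for cluster-scope results).
#' @param window An [analysis_window()].
#' @param catalogue Indicator catalogue (defaults to the shipped one).
#' @param scope,scope_id Labels recorded on the result row.
#' @return A metric-result tibble (see [indicator-computation]).
#' @export
consent_rate <- function(reg, window, catalogue = metric_catalogue(),
                         scope = "site", scope_id = "all") {
  en <- reg$enrollments
  inw <- month_floor(en$enrollment_date) %in% window$months
  den <- sum(inw)
  num <- sum(inw & (en$consent_obtained %|na|% FALSE))
  metric_result("consent_rate", scope, scope_id, window, num, den,
                pct(num, den), catalogue)
}

#' Month-to-month variability factor
#'
#' Highest monthly count divided by the lowest, over exactly six ordered
#' monthly counts. A zero month makes the factor undefined (`NA`): the zero
#' itself is surfaced by the minimum-deliveries indicator, not by an infinite
#' ratio.
#'
#' @param monthly_counts Integer vector of exactly 6 monthly counts.
#' @return The max/min ratio, or `NA` when any month is zero.
#' @export
variability_factor <- function(monthly_counts) {
  if (length(monthly_counts) != 6 || anyNA(monthly_counts))
    abort_regqc("variability factor needs exactly 6 monthly counts",
                "regqc_bad_value")
  if (min(monthly_counts) == 0) return(NA_real_)
  max(monthly_counts) / min(monthly_counts)
}

monthly_counts_for <- function(dates, window) {
  m <- month_floor(dates)
  vapply(window$months, function(mo) sum(m == mo, na.rm = TRUE), numeric(1))
}

#' @rdname variability_factor
#' @param reg,window,catalogue,scope,scope_id See [consent_rate()].
#' @param which `"enrollment"` (count of enrollments by enrollment month) or
#'   `"birth"` (count of live + stillborn infants by delivery month).
#' @export
variability_metric <- function(reg, window, which = c("enrollment", "birth"),
                               catalogue = metric_catalogue(),
                               scope = "site", scope_id = "all") {
  which <- match.arg(which)
  if (length(window$months) != 6) {
    counts <- NULL
  } else if (which == "enrollment") {
    counts <- monthly_counts_for(reg$enrollments$enrollment_date, window)
  } else {
    bd <- births_dated(reg)
    bd <- bd[bd$status %in% c("live_birth", "stillbirth"), ]
    counts <- monthly_counts_for(bd$delivery_date, window)
  }
  value <- if (is.null(counts)) NA_real_ else variability_factor(counts)
  id <- if (which == "enrollment") "enroll_variability" else "birth_variability"
  metric_result(id, scope, scope_id, window,
                if (is.null(counts)) NA else max(counts),
                if (is.null(counts)) NA else min(counts),
                value, catalogue)
}

#' Expected delivery outcomes obtained
#'
#' Denominator: consented enrollments whose EDD falls in the window and whose
#' EDD plus the grace period has passed by the window end (the pregnancy is
#' *expected* to have delivered). Numerator: those with a delivery form.
#'
#' @inheritParams consent_rate
#' @param edd_grace_days Days past the EDD before a delivery is considered
#'   overdue (default 42).
#' @export
delivery_outcome_proportion <- function(reg, window,
                                        catalogue = metric_catalogue(),
                                        scope = "site", scope_id = "all",
                                        edd_grace_days = 42) {
  en <- reg$enrollments
  expected <- (en$consent_obtained %|na|% FALSE) & !is.na(en$edd) &
    month_floor(en$edd) %in% window$months &
    (en$edd + edd_grace_days) <= window$end_day
  den <- sum(expected)
  num <- sum(expected & en$study_id %in% reg$deliveries$study_id)
  metric_result("delivery_outcome", scope, scope_id, window, num, den,
                pct(num, den), catalogue)
}

#' Six-week outcome obtained
#'
#' Denominator: deliveries in the window that are *due* for the six-week
#' visit (delivery date + 42 days + grace before the window end). Numerator:
#' those with a follow-up form on which at least one infant status is not
#' "lost". A pregnancy lost to follow-up therefore does not count as an
#' outcome obtained even though a form exists.
#'
#' @inheritParams consent_rate
#' @param followup_grace_days Days past the six-week visit date before the
#'   follow-up is considered overdue (default 21).
#' @export
followup_outcome_proportion <- function(reg, window,
                                        catalogue = metric_catalogue(),
                                        scope = "site", scope_id = "all",
                                        followup_grace_days = 21) {
  dl <- reg$deliveries
  due <- month_floor(dl$delivery_date) %in% window$months &
    (dl$delivery_date + 42 + followup_grace_days) <= window$end_day
  den <- sum(due)
  fu <- reg$followups
  obtained_ids <- fu$study_id[
    !vapply(strsplit(fu$infant_status_42d %|na|% "lost", "\\|"),
            function(s) all(s == "lost"), logical(1))]
  num <- sum(due & dl$study_id %in% obtained_ids)
  metric_result("followup_outcome", scope, scope_id, window, num, den,
                pct(num, den), catalogue)
}

#' Sex ratio at birth
#'
#' Males per female among live and stillborn infants with known sex delivered
#' in the window. Undefined when no female births are recorded.
#' @inheritParams consent_rate
#' @export
sex_ratio <- function(reg, window, catalogue = metric_catalogue(),
                      scope = "site", scope_id = "all") {
  bd <- births_dated(reg)
  inw <- bd$status %in% c("live_birth", "stillbirth") &
    month_floor(bd$delivery_date) %in% window$months
  males <- sum(inw & bd$sex == "male")
  females <- sum(inw & bd$sex == "female")
  metric_result("sex_ratio", scope, scope_id, window, males, females,
                ratio_of(males, females), catalogue)
}

#' Enrollment pipeline vs historical deliveries
#'
#' Average expected deliveries per month over the next six months (consented,
#' not-yet-delivered pregnancies by EDD month) as a percentage of the mean
#' monthly delivery count over the preceding twelve calendar months.
#'
#' @inheritParams consent_rate
#' @param as_of_month Month the projection is made from (`Date` or
#'   `"YYYY-MM"`).
#' @export
expected_deliveries_ratio <- function(reg, as_of_month,
                                      catalogue = metric_catalogue(),
                                      scope = "site", scope_id = "all") {
  as_of <- as_month(as_of_month)
  future <- month_seq(month_add(as_of, 1L), month_add(as_of, 6L))
  en <- reg$enrollments
  pipeline <- (en$consent_obtained %|na|% FALSE) & !is.na(en$edd) &
    month_floor(en$edd) %in% future &
    !(en$study_id %in% reg$deliveries$study_id)
  hist <- month_seq(month_add(as_of, -11L), as_of)
  n_hist <- sum(month_floor(reg$deliveries$delivery_date) %in% hist)
  num <- sum(pipeline) / 6
  den <- n_hist / 12
  window <- analysis_window(as_of, 12)
  metric_result("expected_deliveries", scope, scope_id, window, num, den,
                if (den > 0) 100 * num / den else NA_real_, catalogue)
}

#' Minimum monthly deliveries
#'
#' Count of deliveries in a single calendar month, flagged against the
#' required monthly minimum. A month with zero deliveries is a *finding*
#' (value 0, out of range), not missing data — unless the unit has no
#' delivery history at all, in which case there is nothing to measure and
#' the result is `insufficient_data`.
#' @inheritParams consent_rate
#' @param month The calendar month to count.
#' @export
min_deliveries_check <- function(reg, month, catalogue = metric_catalogue(),
                                 scope = "site", scope_id = "all") {
  window <- analysis_window(month, 1)
  n <- sum(month_floor(reg$deliveries$delivery_date) %in% window$months)
  # a unit with no delivery history at all has no data, not a zero month
  value <- if (nrow(reg$deliveries) == 0) NA_real_ else n
  metric_result("min_deliveries", scope, scope_id, window, n, NA_real_, value,
                catalogue)
}

#' Mortality consistency ratios
#'
#' Two ratios over births delivered in the window: stillbirths to early
#' neonatal deaths (death before day 7 of life), and early neonatal deaths to
#' all six-week neonatal deaths (death by day 42; early deaths are a subset).
#' Values far outside the acceptable ranges typically indicate misclassified
#' deaths rather than true epidemiology.
#' @inheritParams consent_rate
#' @return A two-row metric-result tibble.
#' @export
mortality_ratios <- function(reg, window, catalogue = metric_catalogue(),
                             scope = "site", scope_id = "all") {
  bd <- births_dated(reg)
  inw <- month_floor(bd$delivery_date) %in% window$months
  sb <- sum(inw & bd$status == "stillbirth")
  live <- inw & bd$status == "live_birth" & !is.na(bd$death_day_of_life)
  end <- sum(live & bd$death_day_of_life <= 6)
  sixwk <- sum(live & bd$death_day_of_life <= 42)
  dplyr::bind_rows(
    metric_result("sb_end_ratio", scope, scope_id, window, sb, end,
                  ratio_of(sb, end), catalogue),
    metric_result("end_sixwk_ratio", scope, scope_id, window, end, sixwk,
                  ratio_of(end, sixwk), catalogue)
  )
}

#' Classify one miscarriage record for internal consistency
#'
#' A miscarriage should have gestational age under 20 weeks and a (measured
#' or estimated) weight under 500 g; records meeting both are `consistent`,
#' records failing either are `inconsistent`, and records missing either
#' quantity are `unassessable`.
#'
#' @param gestational_age_weeks,birth_weight_grams Values from the linked
#'   delivery and birth records (`NA` when missing).
#' @return `"consistent"`, `"inconsistent"` or `"unassessable"` (vectorised).
#' @export
classify_miscarriage <- function(gestational_age_weeks, birth_weight_grams) {
  ifelse(is.na(gestational_age_weeks) | is.na(birth_weight_grams),
         "unassessable",
         ifelse(gestational_age_weeks < 20 & birth_weight_grams < 500,
                "consistent", "inconsistent"))
}

#' @rdname classify_miscarriage
#' @inheritParams consent_rate
#' @export
miscarriage_consistency <- function(reg, window,
                                    catalogue = metric_catalogue(),
                                    scope = "site", scope_id = "all") {
  bd <- births_dated(reg)
  bd <- dplyr::left_join(
    bd, reg$deliveries[, c("study_id", "gestational_age_weeks")],
    by = "study_id")
  mc <- bd[bd$status == "miscarriage" &
             month_floor(bd$delivery_date) %in% window$months, ]
  cls <- classify_miscarriage(mc$gestational_age_weeks, mc$birth_weight_grams)
  den <- sum(cls != "unassessable")
  num <- sum(cls == "consistent")
  metric_result("miscarriage_consistency", scope, scope_id, window, num, den,
                pct(num, den), catalogue)
}

#' Birth-weight capture by outcome class
#'
#' For each of three (overlapping) outcome classes — live births, neonatal
#' deaths (live births dying by day 42) and stillbirths — the percent with a
#' *measured* weight and the percent with *any* (measured or estimated)
#' weight, plus the three-way source breakdown (measured / estimated /
#' missing, summing to 100%) over all live and stillborn infants.
#'
#' @inheritParams consent_rate
#' @return A six-row metric-result tibble with a `breakdown` attribute
#'   (tibble with columns `source`, `n`, `pct`).
#' @export
birthweight_metrics <- function(reg, window, catalogue = metric_catalogue(),
                                scope = "site", scope_id = "all") {
  bd <- births_dated(reg)
  bd <- bd[month_floor(bd$delivery_date) %in% window$months, ]
  classes <- list(
    live = bd$status == "live_birth",
    neonatal_death = bd$status == "live_birth" &
      !is.na(bd$death_day_of_life) & bd$death_day_of_life <= 42,
    stillbirth = bd$status == "stillbirth"
  )
  rows <- list()
  for (cl in names(classes)) {
    sel <- classes[[cl]]
    den <- sum(sel)
    meas <- sum(sel & bd$birth_weight_source == "measured")
    any_bw <- sum(sel & bd$birth_weight_source != "missing")
    rows <- c(rows, list(
      metric_result(paste0("bw_measured_", cl), scope, scope_id, window,
                    meas, den, pct(meas, den), catalogue),
      metric_result(paste0("bw_any_", cl), scope, scope_id, window,
                    any_bw, den, pct(any_bw, den), catalogue)
    ))
  }
  out <- dplyr::bind_rows(rows)
  reg_births <- bd[bd$status %in% c("live_birth", "stillbirth"), ]
  n <- nrow(reg_births)
  breakdown <- tibble::tibble(
    source = c("measured", "estimated", "missing"),
    n = vapply(c("measured", "estimated", "missing"),
               function(s) sum(reg_births$birth_weight_source == s),
               numeric(1), USE.NAMES = FALSE)
  )
  breakdown$pct <- if (n > 0) 100 * breakdown$n / n else NA_real_
  attr(out, "breakdown") <- breakdown
  out
}

#' Key-field completeness
#'
#' Conjunctive completeness of the monitored field sets: maternal height,
#' weight and anthropometry timing on enrollment forms, and delivery
#' attendant, location, mode, bag-and-mask use and gestational age on
#' delivery forms. A record counts complete only if *all* named fields are
#' recorded. Pregnancies ending in miscarriage are excluded from the
#' delivery-field denominator (delivery mode and resuscitation do not apply).
#'
#' @inheritParams consent_rate
#' @return A two-row metric-result tibble.
#' @export
key_field_completeness <- function(reg, window,
                                   catalogue = metric_catalogue(),
                                   scope = "site", scope_id = "all") {
  en <- reg$enrollments
  inw <- month_floor(en$enrollment_date) %in% window$months
  den_a <- sum(inw)
  num_a <- sum(inw & (en$maternal_height_recorded %|na|% FALSE) &
                 (en$maternal_weight_recorded %|na|% FALSE) &
                 (en$anthropometry_timing_recorded %|na|% FALSE))

  dl <- reg$deliveries
  non_misc_ids <- unique(reg$births$study_id[reg$births$status != "miscarriage"])
  misc_ids <- unique(reg$births$study_id[reg$births$status == "miscarriage"])
  misc_only <- dl$study_id %in% setdiff(misc_ids, non_misc_ids)
  eligible <- month_floor(dl$delivery_date) %in% window$months & !misc_only
  den_d <- sum(eligible)
  num_d <- sum(eligible &
                 dl$delivery_attendant != "missing" &
                 dl$delivery_location != "missing" &
                 dl$delivery_mode != "missing" &
                 dl$bag_and_mask_used != "missing" &
                 !is.na(dl$gestational_age_weeks))
  dplyr::bind_rows(
    metric_result("maternal_anthro_complete", scope, scope_id, window,
                  num_a, den_a, pct(num_a, den_a), catalogue),
    metric_result("delivery_fields_complete", scope, scope_id, window,
                  num_d, den_d, pct(num_d, den_d), catalogue)
  )
}

#' Process timeliness indicators
#'
#' Latency indicators over the forms whose anchor event falls in the window.
#' Day gaps use the strict/inclusive operators printed in the monitoring
#' protocol: "less than 4 weeks" means gap < 28 days, "between 5 and 9
#' weeks" means 35-63 days inclusive, "within 7 days" means gap <= 7.
#' Records with either date missing are excluded from the denominator and
#' counted in the `missing_dates` attribute (a per-indicator tally).
#'
#' The weight-recording latency indicator reports the *median* day gap
#' between birth and weight measurement (flagged against the 7-day target);
#' its companion percent-within-7-days indicator is `bw_within_7d`.
#'
#' @inheritParams consent_rate
#' @return A nine-row metric-result tibble (the latency indicators plus the
#'   within-7-days key-variable companion; critical-edit resolution is
#'   computed by [critical_edits_addressed()]) with a `missing_dates`
#'   attribute.
#' @export
process_timeliness <- function(reg, window, catalogue = metric_catalogue(),
                               scope = "site", scope_id = "all") {
  en <- reg$enrollments
  en <- en[month_floor(en$enrollment_date) %in% window$months, ]
  dl <- reg$deliveries
  dl <- dl[month_floor(dl$delivery_date) %in% window$months, ]
  fu <- dplyr::inner_join(
    reg$followups, dl[, c("study_id", "delivery_date")], by = "study_id")
  bd <- births_dated(reg)
  bd <- bd[bd$status %in% c("live_birth", "stillbirth") &
             month_floor(bd$delivery_date) %in% window$months, ]

  missing_tally <- list()
  prop_metric <- function(id, from, to, ok) {
    have <- !is.na(from) & !is.na(to)
    missing_tally[[id]] <<- sum(!have)
    gap <- days_between(from[have], to[have])
    den <- sum(have)
    num <- sum(ok(gap))
    metric_result(id, scope, scope_id, window, num, den, pct(num, den),
                  catalogue)
  }

  have_bw <- !is.na(bd$weight_record_date) & !is.na(bd$delivery_date) &
    bd$birth_weight_source != "missing"
  missing_tally[["bw_recording_latency"]] <- sum(!have_bw)
  bw_gap <- days_between(bd$delivery_date[have_bw], bd$weight_record_date[have_bw])
  latency <- metric_result(
    "bw_recording_latency", scope, scope_id, window,
    sum(bw_gap < 7), sum(have_bw),
    if (sum(have_bw) > 0) stats::median(bw_gap) else NA_real_, catalogue)
  within7 <- metric_result(
    "bw_within_7d", scope, scope_id, window,
    sum(bw_gap <= 7), sum(have_bw),
    pct(sum(bw_gap <= 7), sum(have_bw)), catalogue)
  missing_tally[["bw_within_7d"]] <- sum(!have_bw)

  out <- dplyr::bind_rows(
    latency,
    within7,
    prop_metric("enroll_entry_6wk", en$enrollment_date,
                en$enrollment_data_entry_date, function(g) g < 42),
    prop_metric("enroll_edd_4wk", en$enrollment_date, en$edd,
                function(g) g > 28),
    prop_metric("delivery_collection_entry_6wk",
                dl$delivery_form_completion_date, dl$delivery_data_entry_date,
                function(g) g < 42),
    prop_metric("delivery_form_4wk", dl$delivery_date,
                dl$delivery_form_completion_date, function(g) g < 28),
    prop_metric("delivery_form_entry_6wk", dl$delivery_form_completion_date,
                dl$delivery_data_entry_date, function(g) g < 42),
    prop_metric("followup_form_5_9wk", fu$delivery_date,
                fu$followup_form_completion_date,
                function(g) g >= 35 & g <= 63),
    prop_metric("followup_entry_6wk", fu$followup_form_completion_date,
                fu$followup_data_entry_date, function(g) g < 42)
  )
  attr(out, "missing_dates") <- tibble::tibble(
    metric_id = names(missing_tally),
    n_missing_dates = unlist(missing_tally, use.names = FALSE))
  out
}

#' Critical-edit resolution
#'
#' Percent of critical edit items raised during the window that have been
#' addressed by computation time.
#' @inheritParams consent_rate
#' @export
critical_edits_addressed <- function(reg, window,
                                     catalogue = metric_catalogue(),
                                     scope = "site", scope_id = "all") {
  ed <- reg$edits
  inw <- ed$severity == "critical" &
    month_floor(ed$raised_date) %in% window$months
  den <- sum(inw)
  num <- sum(inw & ed$status == "addressed")
  metric_result("critical_edits", scope, scope_id, window, num, den,
                pct(num, den), catalogue)
}

#' Compute the full indicator battery
#'
#' Runs every catalogued indicator per cluster and for the pooled site over
#' the windows the monitoring protocol prescribes: a trailing window
#' (`span_months`, default 6) for rolling indicators, the report month alone
#' for the minimum-deliveries check, and the report month as the projection
#' origin for the enrollment-pipeline indicator. Site-scope values pool
#' numerators and denominators over clusters (never averages of cluster
#' values).
#'
#' @param reg A [registry_tables()] extract.
#' @param as_of_month Report month (`Date` or `"YYYY-MM"`).
#' @param catalogue Indicator catalogue.
#' @param scope Character vector among `"cluster"`, `"site"`.
#' @param span_months Trailing window length for rolling indicators.
#' @param site_id Label used for the site-scope rows.
#' @param edd_grace_days,followup_grace_days See
#'   [delivery_outcome_proportion()] and [followup_outcome_proportion()].
#' @return A metric-result tibble, one row per (scope unit, indicator).
#' @export
compute_metrics <- function(reg, as_of_month,
                            catalogue = metric_catalogue(),
                            scope = c("cluster", "site"),
                            span_months = 6, site_id = "site",
                            edd_grace_days = 42, followup_grace_days = 21) {
  scope <- match.arg(scope, several.ok = TRUE)
  window <- analysis_window(as_of_month, span_months)
  units <- list()
  if ("cluster" %in% scope) {
    for (cl in sort(unique(reg$enrollments$cluster_id)))
      units[[length(units) + 1]] <- list(scope = "cluster", id = cl,
                                         reg = filter_cluster(reg, cl))
  }
  if ("site" %in% scope)
    units[[length(units) + 1]] <- list(scope = "site", id = site_id, reg = reg)

  one_unit <- function(u) {
    dplyr::bind_rows(
      consent_rate(u$reg, window, catalogue, u$scope, u$id),
      variability_metric(u$reg, window, "enrollment", catalogue, u$scope, u$id),
      variability_metric(u$reg, window, "birth", catalogue, u$scope, u$id),
      delivery_outcome_proportion(u$reg, window, catalogue, u$scope, u$id,
                                  edd_grace_days),
      followup_outcome_proportion(u$reg, window, catalogue, u$scope, u$id,
                                  followup_grace_days),
      sex_ratio(u$reg, window, catalogue, u$scope, u$id),
      expected_deliveries_ratio(u$reg, as_of_month, catalogue, u$scope, u$id),
      min_deliveries_check(u$reg, as_of_month, catalogue, u$scope, u$id),
      mortality_ratios(u$reg, window, catalogue, u$scope, u$id),
      miscarriage_consistency(u$reg, window, catalogue, u$scope, u$id),
      birthweight_metrics(u$reg, window, catalogue, u$scope, u$id),
      key_field_completeness(u$reg, window, catalogue, u$scope, u$id),
      process_timeliness(u$reg, window, catalogue, u$scope, u$id),
      critical_edits_addressed(u$reg, window, catalogue, u$scope, u$id)
    )
  }
  dplyr::bind_rows(lapply(units, one_unit))
}
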
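#' Default edit-check rule set
#'
#' The shipped rules emulate a data-coordinating-center edit report: range
#' checks on single fields, a skip check (a question answered that should
#' have been skipped), cross-form consistency checks, and
#' missing-expected-form checks driven by the EDD and the delivery date.
#' Range bounds and severities are site policy, not physiology, and can be
#' edited: rules round-trip through a plain CSV via [read_check_rules()] /
#' [write_check_rules()]. Severity follows the convention that
#' missing-expected-form and mortality-consistency findings are critical
#' while single-field range violations are not.
#'
#' @return A tibble with columns `rule_id`, `check_type`, `form`,
#'   `field_name`, `lower`, `upper`, `horizon_days`, `severity`.
#' @export
default_check_rules <- function() {
  tibble::tribble(
    ~rule_id, ~check_type, ~form, ~field_name, ~lower, ~upper, ~horizon_days,
      ~severity,
    "ga_range", "range", "delivery", "gestational_age_weeks", 4, 46, NA,
      "noncritical",
    "bw_range", "range", "delivery", "birth_weight_grams", 200, 6500, NA,
      "noncritical",
    "bag_mask_miscarriage", "skip", "delivery", "bag_and_mask_used", NA, NA,
      NA, "noncritical",
    "stillbirth_death_day", "cross_form", "delivery", "death_day_of_life",
      NA, NA, NA, "critical",
    "delivery_without_consent", "cross_form", "delivery", "consent_obtained",
      NA, NA, NA, "critical",
    "miscarriage_inconsistent", "cross_form", "delivery",
      "gestational_age_weeks|birth_weight_grams", NA, NA, NA, "critical",
    "missing_delivery_form", "missing_expected_form", "delivery", NA,
      NA, NA, 42, "critical",
    "missing_followup_form", "missing_expected_form", "followup", NA,
      NA, NA, 63, "critical"
  )
}

#' @rdname default_check_rules
#' @param path CSV file path.
#' @export
read_check_rules <- function(path) {
  if (!file.exists(path))
    abort_regqc(paste("file not found:", path), "regqc_missing_file")
  rules <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  proto <- default_check_rules()
  if (!setequal(names(rules), names(proto)))
    abort_regqc("rules file does not match the documented rule schema",
                "regqc_bad_config")
  unknown <- setdiff(rules$rule_id, proto$rule_id)
  if (length(unknown) > 0)
    abort_regqc(paste("unknown rule_id(s):", paste(unknown, collapse = ", ")),
                "regqc_bad_config")
  rules <- rules[names(proto)]
  for (col in c("lower", "upper", "horizon_days"))
    rules[[col]] <- as.numeric(rules[[col]])
  for (col in c("rule_id", "check_type", "form", "field_name", "severity"))
    rules[[col]] <- as.character(rules[[col]])
  rules
}

#' @rdname default_check_rules
#' @param rules A rule tibble.
#' @export
write_check_rules <- function(rules, path) {
  readr::write_csv(rules, path, progress = FALSE)
  invisible(path)
}

#' Run edit checks over a registry extract
#'
#' Applies the rule set and emits one edit item per (record, rule)
#' violation, with stable ordering by `study_id` then `rule_id` so the same
#' extract always yields byte-identical edit reports. Missing-expected-form
#' checks need to know "today": `as_of` defaults to the latest date present
#' anywhere in the extract.
#'
#' @param reg A [registry_tables()] extract.
#' @param rules A rule tibble (see [default_check_rules()]).
#' @param as_of Reference date for overdue-form checks.
#' @return An edit-item tibble in the `edits` table schema, all `open`, with
#'   `raised_date = as_of`.
#' @export
run_checks <- function(reg, rules = default_check_rules(), as_of = NULL) {
  stopifnot(inherits(reg, "registry_tables"))
  known <- default_check_rules()$rule_id
  unknown <- setdiff(rules$rule_id, known)
  if (length(unknown) > 0)
    abort_regqc(paste("unknown rule_id(s):", paste(unknown, collapse = ", ")),
                "regqc_bad_config")
  if (is.null(as_of)) {
    # latest *event* date: entry dates can postdate the extract period and
    # EDDs of the enrollment pipeline lie in the future by design
    dates <- c(reg$enrollments$enrollment_date, reg$deliveries$delivery_date)
    as_of <- if (all(is.na(dates))) Sys.Date() else max(dates, na.rm = TRUE)
  }
  as_of <- as.Date(as_of)

  items <- list()
  emit <- function(rule, study_id, infant_index = NA_integer_) {
    if (length(study_id) == 0) return(NULL)
    suffix <- ifelse(is.na(infant_index), "", paste0("#", infant_index))
    items[[length(items) + 1]] <<- tibble::tibble(
      edit_id = paste0(rule$rule_id, ":", study_id, suffix),
      study_id = study_id, form = rule$form,
      field_name = rule$field_name %|na|% "",
      check_type = rule$check_type, severity = rule$severity,
      status = "open", raised_date = as_of, resolved_date = as.Date(NA))
  }

  en <- reg$enrollments
  dl <- reg$deliveries
  bi <- births_dated(reg)
  bi <- dplyr::left_join(
    bi, dl[, c("study_id", "gestational_age_weeks")], by = "study_id")
  misc_only_ids <- unique(reg$births$study_id[
    !reg$births$study_id %in% reg$births$study_id[reg$births$status != "miscarriage"]])

  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, ]
    switch(rule$rule_id,
      ga_range = {
        x <- dl$gestational_age_weeks
        sel <- !is.na(x) & (x < rule$lower | x > rule$upper)
        emit(rule, dl$study_id[sel])
      },
      bw_range = {
        x <- reg$births$birth_weight_grams
        sel <- !is.na(x) & (x < rule$lower | x > rule$upper)
        emit(rule, reg$births$study_id[sel], reg$births$infant_index[sel])
      },
      bag_mask_miscarriage = {
        sel <- dl$study_id %in% misc_only_ids & dl$bag_and_mask_used != "missing"
        emit(rule, dl$study_id[sel])
      },
      stillbirth_death_day = {
        sel <- reg$births$status == "stillbirth" &
          !is.na(reg$births$death_day_of_life)
        emit(rule, reg$births$study_id[sel], reg$births$infant_index[sel])
      },
      delivery_without_consent = {
        unconsented <- en$study_id[!(en$consent_obtained %|na|% FALSE)]
        sel <- dl$study_id %in% unconsented
        emit(rule, dl$study_id[sel])
      },
      miscarriage_inconsistent = {
        sel <- bi$status == "miscarriage" &
          classify_miscarriage(bi$gestational_age_weeks,
                               bi$birth_weight_grams) == "inconsistent"
        emit(rule, bi$study_id[sel], bi$infant_index[sel])
      },
      missing_delivery_form = {
        sel <- (en$consent_obtained %|na|% FALSE) & !is.na(en$edd) &
          (en$edd + rule$horizon_days) <= as_of &
          !(en$study_id %in% dl$study_id)
        emit(rule, en$study_id[sel])
      },
      missing_followup_form = {
        sel <- (dl$delivery_date + rule$horizon_days) <= as_of &
          !(dl$study_id %in% reg$followups$study_id)
        emit(rule, dl$study_id[sel])
      },
      abort_regqc(paste("unknown rule_id:", rule$rule_id), "regqc_bad_config")
    )
  }
  out <- dplyr::bind_rows(c(list(edit_prototype()), items))
  out[order(out$study_id, out$edit_id), ]
}

#' Mark edit items as addressed
#'
#' Idempotent: re-resolving an already-addressed item changes nothing (its
#' original resolution date is kept).
#'
#' @param edits An edit-item tibble.
#' @param edit_ids Character vector of `edit_id`s to resolve.
#' @param resolved_date Resolution date (default today).
#' @return The updated edit-item tibble.
#' @export
resolve_edits <- function(edits, edit_ids, resolved_date = Sys.Date()) {
  unknown <- setdiff(edit_ids, edits$edit_id)
  if (length(unknown) > 0)
    abort_regqc(paste("unknown edit_id(s):", paste(unknown, collapse = ", ")),
                "regqc_unknown_edit")
  sel <- edits$edit_id %in% edit_ids & edits$status == "open"
  edits$status[sel] <- "addressed"
  edits$resolved_date[sel] <- pmax(as.Date(resolved_date),
                                   edits$raised_date[sel])
  edits
}
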
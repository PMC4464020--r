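#' Defect-injection configuration
#'
#' Each rate is the independent per-record probability that the named quality
#' defect is applied to an eligible record. Defects corrupt values (missing,
#' misdated, misclassified) but never produce structurally malformed rows,
#' so a corrupted extract still loads and validates.
#'
#' * `drop_birth_weight` — birth weight (value, source and record date) lost.
#' * `downgrade_measured_to_estimated` — a measured weight recorded as
#'   estimated instead.
#' * `misclassify_end_as_stillbirth` — an early neonatal death recorded as a
#'   stillbirth (day of death cleared).
#' * `drop_followup_record` — the six-week form never reaches the database.
#' * `delay_data_entry` — extra days added to a form's data-entry date
#'   (`delay_days` log-normal distribution).
#' * `drop_consent_flag` — consent not documented on the enrollment form.
#' * `miss_enrollment` — the pregnancy is only identified at delivery:
#'   enrollment and its form dates collapse onto the delivery date.
#' * `drop_key_delivery_fields` — the five monitored delivery-form fields
#'   (attendant, location, mode, bag-and-mask, gestational age) lost.
#'
#' @param drop_birth_weight,downgrade_measured_to_estimated,misclassify_end_as_stillbirth,drop_followup_record,delay_data_entry,drop_consent_flag,miss_enrollment,drop_key_delivery_fields
#'   Rates in \[0, 1\] (default 0).
#' @param delay_days Log-normal `list(meanlog, sdlog)` of added entry days.
#' @return A `defect_config` list.
#' @export
defect_config <- function(drop_birth_weight = 0,
                          downgrade_measured_to_estimated = 0,
                          misclassify_end_as_stillbirth = 0,
                          drop_followup_record = 0,
                          delay_data_entry = 0,
                          drop_consent_flag = 0,
                          miss_enrollment = 0,
                          drop_key_delivery_fields = 0,
                          delay_days = list(meanlog = log(60), sdlog = 0.3)) {
  cfg <- as.list(environment())
  rates <- unlist(cfg[setdiff(names(cfg), "delay_days")])
  if (any(rates < 0 | rates > 1))
    abort_regqc("defect rates must lie in [0, 1]", "regqc_bad_config")
  class(cfg) <- "defect_config"
  cfg
}

#' Names of the defect knobs
#' @return Character vector of the eight defect-rate names.
#' @export
defect_types <- function() {
  c("drop_birth_weight", "downgrade_measured_to_estimated",
    "misclassify_end_as_stillbirth", "drop_followup_record",
    "delay_data_entry", "drop_consent_flag", "miss_enrollment",
    "drop_key_delivery_fields")
}

#' Inject quality defects into a registry extract
#'
#' Applies each configured defect independently, per eligible record, with
#' its configured rate. Returns the corrupted extract with a `defect_ledger`
#' attribute listing every record touched (`defect`, `table`, `study_id`,
#' `infant_index`), which exactly accounts for the differences between input
#' and output.
#'
#' @param reg A [registry_tables()] extract.
#' @param defects A [defect_config()].
#' @param seed Integer seed for the defect draws.
#' @return The corrupted extract (still a valid `registry_tables`).
#' @export
inject_defects <- function(reg, defects = defect_config(), seed = 1L) {
  stopifnot(inherits(reg, "registry_tables"), inherits(defects, "defect_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  ledger <- list()
  note <- function(defect, table, study_id, infant_index = NA_integer_) {
    if (length(study_id) == 0) return(NULL)
    ledger[[length(ledger) + 1]] <<- tibble::tibble(
      defect = defect, table = table, study_id = study_id,
      infant_index = as.integer(infant_index))
  }
  hit <- function(n, rate) runif(n) < rate

  bi <- reg$births
  sel <- hit(nrow(bi), defects$drop_birth_weight) &
    bi$birth_weight_source != "missing"
  bi$birth_weight_grams[sel] <- NA_real_
  bi$birth_weight_source[sel] <- "missing"
  bi$weight_record_date[sel] <- as.Date(NA)
  note("drop_birth_weight", "births", bi$study_id[sel], bi$infant_index[sel])

  sel <- hit(nrow(bi), defects$downgrade_measured_to_estimated) &
    bi$birth_weight_source == "measured"
  bi$birth_weight_source[sel] <- "estimated"
  note("downgrade_measured_to_estimated", "births",
       bi$study_id[sel], bi$infant_index[sel])

  sel <- hit(nrow(bi), defects$misclassify_end_as_stillbirth) &
    bi$status == "live_birth" &
    !is.na(bi$death_day_of_life) & bi$death_day_of_life <= 6
  bi$status[sel] <- "stillbirth"
  bi$death_day_of_life[sel] <- NA_integer_
  note("misclassify_end_as_stillbirth", "births",
       bi$study_id[sel], bi$infant_index[sel])
  reg$births <- bi

  fu <- reg$followups
  sel <- hit(nrow(fu), defects$drop_followup_record)
  note("drop_followup_record", "followup", fu$study_id[sel])
  reg$followups <- fu[!sel, ]

  dd <- defects$delay_days
  en <- reg$enrollments
  sel <- hit(nrow(en), defects$delay_data_entry)
  en$enrollment_data_entry_date[sel] <- en$enrollment_data_entry_date[sel] +
    rlnorm_days(sum(sel), dd)
  note("delay_data_entry", "enrollment", en$study_id[sel])
  dl <- reg$deliveries
  sel <- hit(nrow(dl), defects$delay_data_entry)
  dl$delivery_data_entry_date[sel] <- dl$delivery_data_entry_date[sel] +
    rlnorm_days(sum(sel), dd)
  note("delay_data_entry", "delivery", dl$study_id[sel])
  fu <- reg$followups
  sel <- hit(nrow(fu), defects$delay_data_entry)
  fu$followup_data_entry_date[sel] <- fu$followup_data_entry_date[sel] +
    rlnorm_days(sum(sel), dd)
  note("delay_data_entry", "followup", fu$study_id[sel])
  reg$followups <- fu

  sel <- hit(nrow(en), defects$drop_consent_flag) & en$consent_obtained
  en$consent_obtained[sel] <- FALSE
  note("drop_consent_flag", "enrollment", en$study_id[sel])

  delivered <- match(en$study_id, dl$study_id)
  sel <- hit(nrow(en), defects$miss_enrollment) & !is.na(delivered)
  if (any(sel)) {
    ddate <- dl$delivery_date[delivered[sel]]
    entry_lag <- pmax(days_between(en$enrollment_form_completion_date[sel],
                                   en$enrollment_data_entry_date[sel]), 0L)
    en$enrollment_date[sel] <- ddate
    en$enrollment_form_completion_date[sel] <- ddate
    en$enrollment_data_entry_date[sel] <- ddate + entry_lag
  }
  note("miss_enrollment", "enrollment", en$study_id[sel])
  reg$enrollments <- en

  sel <- hit(nrow(dl), defects$drop_key_delivery_fields)
  dl$delivery_attendant[sel] <- "missing"
  dl$delivery_location[sel] <- "missing"
  dl$delivery_mode[sel] <- "missing"
  dl$bag_and_mask_used[sel] <- "missing"
  dl$gestational_age_weeks[sel] <- NA_real_
  note("drop_key_delivery_fields", "delivery", dl$study_id[sel])
  reg$deliveries <- dl

  attr(reg, "defect_ledger") <- dplyr::bind_rows(c(
    list(tibble::tibble(defect = character(), table = character(),
                        study_id = character(), infant_index = integer())),
    ledger))
  reg
}
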
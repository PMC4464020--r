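#' Registry record model
#'
#' A registry extract is a set of five linked tables, carried as tibbles
#' inside a `registry_tables` object:
#'
#' * `enrollments` — one row per consented (or screened) pregnancy.
#' * `deliveries`  — one row per pregnancy with a completed pregnancy-outcome
#'   form (this includes miscarriages, which are recorded on the same form).
#' * `births`      — one row per infant (multiple births allowed), keyed by
#'   `(study_id, infant_index)`.
#' * `followups`   — at most one row per delivered pregnancy, holding the
#'   six-week maternal status and the per-infant six-week statuses (a
#'   `|`-separated string aligned with `infant_index` order).
#' * `edits`       — data-quality findings (see [run_checks()]).
#'
#' Categorical fields use an explicit `"missing"` level rather than `NA` so
#' that "the question was not answered" is distinct from "the row was never
#' entered"; numeric and date fields use `NA`.
#'
#' @name registry-records
NULL

DELIVERY_LOCATIONS <- c("home", "health_center", "hospital", "other", "missing")
DELIVERY_ATTENDANTS <- c("physician", "nurse_midwife", "TBA", "family", "other",
                         "missing")
DELIVERY_MODES <- c("vaginal", "cesarean", "missing")
TRISTATE <- c("yes", "no", "missing")
BIRTH_STATUSES <- c("live_birth", "stillbirth", "miscarriage")
SEXES <- c("male", "female", "missing")
BW_SOURCES <- c("measured", "estimated", "missing")
FU_STATUSES <- c("alive", "died", "lost")
EDIT_FORMS <- c("enrollment", "delivery", "followup")
CHECK_TYPES <- c("range", "skip", "cross_form", "missing_expected_form")
SEVERITIES <- c("critical", "noncritical")
EDIT_STATUSES <- c("open", "addressed")

enrollment_prototype <- function() {
  tibble::tibble(
    study_id = character(), cluster_id = character(),
    consent_obtained = logical(),
    enrollment_date = as.Date(character()), edd = as.Date(character()),
    maternal_height_recorded = logical(), maternal_weight_recorded = logical(),
    anthropometry_timing_recorded = logical(),
    enrollment_form_completion_date = as.Date(character()),
    enrollment_data_entry_date = as.Date(character())
  )
}

delivery_prototype <- function() {
  tibble::tibble(
    study_id = character(), cluster_id = character(),
    delivery_date = as.Date(character()),
    delivery_location = character(), delivery_attendant = character(),
    delivery_mode = character(), bag_and_mask_used = character(),
    gestational_age_weeks = double(),
    delivery_form_completion_date = as.Date(character()),
    delivery_data_entry_date = as.Date(character())
  )
}

birth_prototype <- function() {
  tibble::tibble(
    study_id = character(), infant_index = integer(),
    status = character(), sex = character(),
    birth_weight_grams = double(), birth_weight_source = character(),
    weight_record_date = as.Date(character()),
    death_day_of_life = integer()
  )
}

followup_prototype <- function() {
  tibble::tibble(
    study_id = character(),
    followup_form_completion_date = as.Date(character()),
    followup_data_entry_date = as.Date(character()),
    infant_status_42d = character(), maternal_status_42d = character()
  )
}

edit_prototype <- function() {
  tibble::tibble(
    edit_id = character(), study_id = character(), form = character(),
    field_name = character(), check_type = character(), severity = character(),
    status = character(),
    raised_date = as.Date(character()), resolved_date = as.Date(character())
  )
}

#' Assemble (and validate) a registry extract
#'
#' Bundles the five record tables into a `registry_tables` object. Missing
#' tables default to empty prototypes, so `registry_tables()` is the empty
#' extract. Structural problems (duplicate enrollment `study_id`s, delivery /
#' follow-up / birth rows with no parent row) are errors; rows that violate a
#' record-level invariant are rejected and reported in the `diagnostics`
#' attribute rather than silently dropped.
#'
#' @param enrollments,deliveries,births,followups,edits Data frames using the
#'   column schemas documented in [registry-records].
#' @param validate Validate and reject invariant-violating rows (default TRUE).
#' @return A `registry_tables` list with elements `enrollments`, `deliveries`,
#'   `births`, `followups`, `edits` and a `diagnostics` tibble attribute
#'   (`table`, `row`, `study_id`, `field`, `rule`).
#' @export
registry_tables <- function(enrollments = enrollment_prototype(),
                            deliveries = delivery_prototype(),
                            births = birth_prototype(),
                            followups = followup_prototype(),
                            edits = edit_prototype(),
                            validate = TRUE) {
  reg <- list(
    enrollments = coerce_table(enrollments, enrollment_prototype(), "enrollment"),
    deliveries = coerce_table(deliveries, delivery_prototype(), "delivery"),
    births = coerce_table(births, birth_prototype(), "births"),
    followups = coerce_table(followups, followup_prototype(), "followup"),
    edits = coerce_table(edits, edit_prototype(), "edits")
  )
  class(reg) <- "registry_tables"
  if (validate) reg <- validate_registry(reg) else
    attr(reg, "diagnostics") <- diagnostics_prototype()
  reg
}

diagnostics_prototype <- function() {
  tibble::tibble(table = character(), row = integer(), study_id = character(),
                 field = character(), rule = character())
}

coerce_table <- function(x, proto, name) {
  x <- tibble::as_tibble(x)
  unknown <- setdiff(names(x), names(proto))
  if (length(unknown) > 0) {
    abort_regqc(sprintf("unknown column(s) in %s table: %s", name,
                        paste(unknown, collapse = ", ")),
                "regqc_bad_columns")
  }
  missing <- setdiff(names(proto), names(x))
  if (length(missing) > 0) {
    abort_regqc(sprintf("missing column(s) in %s table: %s", name,
                        paste(missing, collapse = ", ")),
                "regqc_bad_columns")
  }
  x <- x[names(proto)]
  for (col in names(proto)) {
    if (inherits(proto[[col]], "Date")) {
      x[[col]] <- as.Date(x[[col]])
    } else {
      x[[col]] <- methods::as(x[[col]], class(proto[[col]])[1])
    }
  }
  # enum columns: NA means the question went unanswered -> explicit "missing"
  enum_cols <- intersect(names(x), c(
    "delivery_location", "delivery_attendant", "delivery_mode",
    "bag_and_mask_used", "sex", "birth_weight_source"))
  for (col in enum_cols) x[[col]] <- ifelse(is.na(x[[col]]), "missing", x[[col]])
  x
}

# Row-level invariant checks; returns a diagnostics tibble.
row_diagnostics <- function(reg) {
  d <- list()
  note <- function(table, rows, sid, field, rule) {
    if (length(rows) == 0) return(NULL)
    tibble::tibble(table = table, row = as.integer(rows),
                   study_id = sid, field = field, rule = rule)
  }
  en <- reg$enrollments
  bad_enum <- function(x, levels) !is.na(x) & !(x %in% levels)

  i <- which(!is.na(en$enrollment_form_completion_date) &
               en$enrollment_form_completion_date < en$enrollment_date)
  d <- c(d, list(note("enrollment", i, en$study_id[i],
                      "enrollment_form_completion_date",
                      "form completion precedes enrollment date")))
  i <- which(!is.na(en$enrollment_data_entry_date) &
               !is.na(en$enrollment_form_completion_date) &
               en$enrollment_data_entry_date < en$enrollment_form_completion_date)
  d <- c(d, list(note("enrollment", i, en$study_id[i],
                      "enrollment_data_entry_date",
                      "data entry precedes form completion")))
  i <- which(en$consent_obtained %|na|% FALSE & is.na(en$edd))
  d <- c(d, list(note("enrollment", i, en$study_id[i], "edd",
                      "consented record with no EDD")))

  dl <- reg$deliveries
  i <- which(!is.na(dl$delivery_form_completion_date) &
               dl$delivery_form_completion_date < dl$delivery_date)
  d <- c(d, list(note("delivery", i, dl$study_id[i],
                      "delivery_form_completion_date",
                      "form completion precedes delivery date")))
  i <- which(!is.na(dl$delivery_data_entry_date) &
               !is.na(dl$delivery_form_completion_date) &
               dl$delivery_data_entry_date < dl$delivery_form_completion_date)
  d <- c(d, list(note("delivery", i, dl$study_id[i], "delivery_data_entry_date",
                      "data entry precedes form completion")))
  for (spec in list(c("delivery_location"), c("delivery_attendant"),
                    c("delivery_mode"), c("bag_and_mask_used"))) {
    lev <- switch(spec, delivery_location = DELIVERY_LOCATIONS,
                  delivery_attendant = DELIVERY_ATTENDANTS,
                  delivery_mode = DELIVERY_MODES,
                  bag_and_mask_used = TRISTATE)
    i <- which(bad_enum(dl[[spec]], lev))
    d <- c(d, list(note("delivery", i, dl$study_id[i], spec,
                        "value outside documented levels")))
  }
  i <- which(!is.na(dl$gestational_age_weeks) & dl$gestational_age_weeks < 0)
  d <- c(d, list(note("delivery", i, dl$study_id[i], "gestational_age_weeks",
                      "negative gestational age")))

  bi <- reg$births
  i <- which(bad_enum(bi$status, BIRTH_STATUSES))
  d <- c(d, list(note("births", i, bi$study_id[i], "status",
                      "value outside documented levels")))
  i <- which(bad_enum(bi$sex, SEXES))
  d <- c(d, list(note("births", i, bi$study_id[i], "sex",
                      "value outside documented levels")))
  i <- which(xor(bi$birth_weight_source == "missing", is.na(bi$birth_weight_grams)))
  d <- c(d, list(note("births", i, bi$study_id[i], "birth_weight_source",
                      "weight value and source must be missing together")))
  i <- which(!is.na(bi$birth_weight_grams) & bi$birth_weight_grams <= 0)
  d <- c(d, list(note("births", i, bi$study_id[i], "birth_weight_grams",
                      "non-positive birth weight")))
  i <- which(!is.na(bi$death_day_of_life) & bi$status != "live_birth")
  d <- c(d, list(note("births", i, bi$study_id[i], "death_day_of_life",
                      "day of death recorded for a non-live birth")))
  i <- which(!is.na(bi$death_day_of_life) & bi$death_day_of_life < 0)
  d <- c(d, list(note("births", i, bi$study_id[i], "death_day_of_life",
                      "negative day of death")))
  ddate <- reg$deliveries$delivery_date[match(bi$study_id, reg$deliveries$study_id)]
  i <- which(!is.na(bi$weight_record_date) & !is.na(ddate) &
               bi$weight_record_date < ddate)
  d <- c(d, list(note("births", i, bi$study_id[i], "weight_record_date",
                      "weight recorded before delivery")))

  fu <- reg$followups
  i <- which(!is.na(fu$followup_data_entry_date) &
               !is.na(fu$followup_form_completion_date) &
               fu$followup_data_entry_date < fu$followup_form_completion_date)
  d <- c(d, list(note("followup", i, fu$study_id[i], "followup_data_entry_date",
                      "data entry precedes form completion")))
  i <- which(bad_enum(fu$maternal_status_42d, FU_STATUSES))
  d <- c(d, list(note("followup", i, fu$study_id[i], "maternal_status_42d",
                      "value outside documented levels")))
  bad_inf <- vapply(strsplit(fu$infant_status_42d %|na|% "", "\\|"),
                    function(s) any(!(s %in% FU_STATUSES)), logical(1))
  i <- which(!is.na(fu$infant_status_42d) & bad_inf)
  d <- c(d, list(note("followup", i, fu$study_id[i], "infant_status_42d",
                      "value outside documented levels")))

  ed <- reg$edits
  i <- which(xor(ed$status == "addressed", !is.na(ed$resolved_date)))
  d <- c(d, list(note("edits", i, ed$study_id[i], "resolved_date",
                      "resolved date and addressed status must agree")))
  i <- which(!is.na(ed$resolved_date) & ed$resolved_date < ed$raised_date)
  d <- c(d, list(note("edits", i, ed$study_id[i], "resolved_date",
                      "resolution precedes raising")))

  dplyr::bind_rows(c(list(diagnostics_prototype()), d))
}

validate_registry <- function(reg) {
  dup <- reg$enrollments$study_id[duplicated(reg$enrollments$study_id)]
  if (length(dup) > 0) {
    abort_regqc(sprintf("duplicate study_id in enrollment table: %s",
                        paste(unique(dup), collapse = ", ")),
                "regqc_duplicate_id")
  }
  orphan <- setdiff(reg$deliveries$study_id, reg$enrollments$study_id)
  if (length(orphan) > 0) {
    abort_regqc(sprintf("delivery row with no matching enrollment: %s",
                        paste(orphan, collapse = ", ")),
                "regqc_orphan_row")
  }
  dup <- reg$followups$study_id[duplicated(reg$followups$study_id)]
  if (length(dup) > 0) {
    abort_regqc(sprintf("more than one follow-up row for study_id: %s",
                        paste(unique(dup), collapse = ", ")),
                "regqc_duplicate_id")
  }
  orphan <- setdiff(reg$followups$study_id, reg$enrollments$study_id)
  if (length(orphan) > 0) {
    abort_regqc(sprintf("follow-up row with no matching enrollment: %s",
                        paste(orphan, collapse = ", ")),
                "regqc_orphan_row")
  }
  orphan <- setdiff(reg$births$study_id, reg$deliveries$study_id)
  if (length(orphan) > 0) {
    abort_regqc(sprintf("birth row with no matching delivery: %s",
                        paste(orphan, collapse = ", ")),
                "regqc_orphan_row")
  }
  diag <- row_diagnostics(reg)
  if (nrow(diag) > 0) {
    for (tb in unique(diag$table)) {
      nm <- switch(tb, enrollment = "enrollments", delivery = "deliveries",
                   births = "births", followup = "followups", edits = "edits")
      reg[[nm]] <- reg[[nm]][-unique(diag$row[diag$table == tb]), ]
    }
  }
  attr(reg, "diagnostics") <- diag
  reg
}

#' @export
print.registry_tables <- function(x, ...) {
  cat("<registry_tables>\n")
  for (nm in c("enrollments", "deliveries", "births", "followups", "edits"))
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  diag <- attr(x, "diagnostics")
  if (!is.null(diag) && nrow(diag) > 0)
    cat(sprintf("  %d row(s) rejected; see attr(., 'diagnostics')\n", nrow(diag)))
  invisible(x)
}

#' Read a registry extract from delimited files
#'
#' Reads the five comma-separated tables (`enrollment.csv`, `delivery.csv`,
#' `births.csv`, `followup.csv`, `edits.csv`; UTF-8, header row, ISO-8601
#' dates) from a directory or from explicitly named paths, validates them and
#' resolves the `study_id` links. Tables whose file is absent from an explicit
#' `paths` list default to empty.
#'
#' @param dir Directory holding the five standard file names.
#' @param paths Optional named list/vector overriding individual file paths
#'   (names among `enrollment`, `delivery`, `births`, `followup`, `edits`).
#' @return A validated [registry_tables()] object.
#' @export
read_registry_tables <- function(dir = NULL, paths = NULL) {
  std <- c(enrollment = "enrollment.csv", delivery = "delivery.csv",
           births = "births.csv", followup = "followup.csv",
           edits = "edits.csv")
  if (!is.null(dir)) {
    paths <- as.list(file.path(dir, std))
    names(paths) <- names(std)
  }
  paths <- as.list(paths)
  bad <- setdiff(names(paths), names(std))
  if (length(bad) > 0)
    abort_regqc(paste("unknown table name(s):", paste(bad, collapse = ", ")),
                "regqc_bad_table_name")
  read_one <- function(key, proto) {
    p <- paths[[key]]
    if (is.null(p)) return(proto)
    if (!file.exists(p))
      abort_regqc(paste("file not found:", p), "regqc_missing_file")
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE,
                    col_types = readr_spec(proto))
  }
  registry_tables(
    enrollments = read_one("enrollment", enrollment_prototype()),
    deliveries = read_one("delivery", delivery_prototype()),
    births = read_one("births", birth_prototype()),
    followups = read_one("followup", followup_prototype()),
    edits = read_one("edits", edit_prototype())
  )
}

readr_spec <- function(proto) {
  cols <- lapply(proto, function(col) {
    if (inherits(col, "Date")) readr::col_date(format = "%Y-%m-%d")
    else if (is.logical(col)) readr::col_logical()
    else if (is.integer(col)) readr::col_integer()
    else if (is.double(col)) readr::col_double()
    else readr::col_character()
  })
  do.call(readr::cols_only, cols)
}

#' Write a registry extract to delimited files
#'
#' Inverse of [read_registry_tables()]: writes the five tables as CSV with
#' ISO-8601 dates. Reading the files back reproduces the extract
#' field-for-field.
#'
#' @param reg A `registry_tables` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_registry_tables <- function(reg, dir) {
  stopifnot(inherits(reg, "registry_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  std <- c(enrollments = "enrollment.csv", deliveries = "delivery.csv",
           births = "births.csv", followups = "followup.csv",
           edits = "edits.csv")
  out <- character(0)
  for (nm in names(std)) {
    p <- file.path(dir, std[[nm]])
    readr::write_csv(reg[[nm]], p, progress = FALSE)
    out[nm] <- p
  }
  invisible(out)
}
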
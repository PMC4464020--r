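# Hand-buildable fixture helpers. All records are structurally valid; rows
# exercising invariant rejection are built inline in the tests that need them.

iso <- function(x) as.Date(x)

make_enrollment <- function(study_id, cluster_id = "C01",
                            enrollment_date, edd,
                            consent = TRUE,
                            height = TRUE, weight = TRUE, timing = TRUE,
                            completion_lag = 1L, entry_lag = 5L) {
  enrollment_date <- iso(enrollment_date)
  tibble::tibble(
    study_id = study_id, cluster_id = cluster_id,
    consent_obtained = consent,
    enrollment_date = enrollment_date, edd = iso(edd),
    maternal_height_recorded = height, maternal_weight_recorded = weight,
    anthropometry_timing_recorded = timing,
    enrollment_form_completion_date = enrollment_date + completion_lag,
    enrollment_data_entry_date = enrollment_date + completion_lag + entry_lag
  )
}

make_delivery <- function(study_id, cluster_id = "C01", delivery_date,
                          location = "health_center",
                          attendant = "nurse_midwife", mode = "vaginal",
                          bag_mask = "no", ga = 39,
                          completion_lag = 3L, entry_lag = 7L) {
  delivery_date <- iso(delivery_date)
  tibble::tibble(
    study_id = study_id, cluster_id = cluster_id,
    delivery_date = delivery_date,
    delivery_location = location, delivery_attendant = attendant,
    delivery_mode = mode, bag_and_mask_used = bag_mask,
    gestational_age_weeks = ga,
    delivery_form_completion_date = delivery_date + completion_lag,
    delivery_data_entry_date = delivery_date + completion_lag + entry_lag
  )
}

make_birth <- function(study_id, infant_index = 1L, status = "live_birth",
                       sex = "female", weight = 3000,
                       source = if (is.na(weight)) "missing" else "measured",
                       weight_lag = 1L, death_day = NA_integer_,
                       delivery_date = NULL) {
  tibble::tibble(
    study_id = study_id, infant_index = as.integer(infant_index),
    status = status, sex = sex,
    birth_weight_grams = as.numeric(weight), birth_weight_source = source,
    weight_record_date = if (is.null(delivery_date) || is.na(weight))
      as.Date(NA) else iso(delivery_date) + weight_lag,
    death_day_of_life = as.integer(death_day)
  )
}

make_followup <- function(study_id, delivery_date, completion_lag = 45L,
                          entry_lag = 7L, infant_status = "alive",
                          maternal_status = "alive") {
  delivery_date <- iso(delivery_date)
  tibble::tibble(
    study_id = study_id,
    followup_form_completion_date = delivery_date + completion_lag,
    followup_data_entry_date = delivery_date + completion_lag + entry_lag,
    infant_status_42d = infant_status, maternal_status_42d = maternal_status
  )
}

# A randomised small registry (<= ~200 records) spanning 2020, two clusters,
# with missingness sprinkled through every checked field.
random_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(20:60, 1)
  ids <- sprintf("S%03d", seq_len(n))
  clusters <- sample(c("C01", "C02"), n, replace = TRUE)
  enroll <- as.Date("2020-01-01") + sample(0:330, n, replace = TRUE)
  edd <- enroll + sample(40:200, n, replace = TRUE)
  en <- tibble::tibble(
    study_id = ids, cluster_id = clusters,
    consent_obtained = runif(n) < 0.9,
    enrollment_date = enroll, edd = edd,
    maternal_height_recorded = runif(n) < 0.9,
    maternal_weight_recorded = runif(n) < 0.9,
    anthropometry_timing_recorded = runif(n) < 0.9,
    enrollment_form_completion_date = enroll + sample(0:10, n, replace = TRUE)
  )
  en$enrollment_data_entry_date <- en$enrollment_form_completion_date +
    sample(0:60, n, replace = TRUE)

  delivered <- runif(n) < 0.8
  dl_ids <- ids[delivered]
  nd <- length(dl_ids)
  ddate <- edd[delivered] + sample(-20:20, nd, replace = TRUE)
  dl <- tibble::tibble(
    study_id = dl_ids, cluster_id = clusters[delivered],
    delivery_date = ddate,
    delivery_location = sample(c("home", "hospital", "missing"), nd, TRUE),
    delivery_attendant = sample(c("TBA", "physician", "missing"), nd, TRUE),
    delivery_mode = sample(c("vaginal", "cesarean", "missing"), nd, TRUE),
    bag_and_mask_used = sample(c("yes", "no", "missing"), nd, TRUE),
    gestational_age_weeks = ifelse(runif(nd) < 0.85,
                                   round(runif(nd, 15, 43), 1), NA),
    delivery_form_completion_date = ddate + sample(0:45, nd, replace = TRUE)
  )
  dl$delivery_data_entry_date <- dl$delivery_form_completion_date +
    sample(0:60, nd, replace = TRUE)

  twins <- 1L + (runif(nd) < 0.1)
  bi <- dplyr::bind_rows(lapply(seq_len(nd), function(i) {
    k <- twins[i]
    status <- sample(c("live_birth", "stillbirth", "miscarriage"), k, TRUE,
                     prob = c(0.7, 0.2, 0.1))
    has_w <- runif(k) < 0.8
    w <- ifelse(has_w, round(runif(k, 300, 4500)), NA)
    death <- ifelse(status == "live_birth" & runif(k) < 0.25,
                    sample(0:50, k, replace = TRUE), NA)
    tibble::tibble(
      study_id = dl_ids[i], infant_index = seq_len(k),
      status = status,
      sex = sample(c("male", "female", "missing"), k, TRUE,
                   prob = c(0.45, 0.45, 0.1)),
      birth_weight_grams = as.numeric(w),
      birth_weight_source = ifelse(has_w,
                                   sample(c("measured", "estimated"), k, TRUE),
                                   "missing"),
      weight_record_date = dplyr::if_else(has_w & runif(k) < 0.9,
                                          dl$delivery_date[i] +
                                            sample(0:12, k, replace = TRUE),
                                          as.Date(NA)),
      death_day_of_life = as.integer(death)
    )
  }))

  fu_sel <- which(runif(nd) < 0.8)
  fu <- dplyr::bind_rows(lapply(fu_sel, function(i) {
    k <- twins[i]
    make_followup(dl_ids[i], dl$delivery_date[i],
                  completion_lag = sample(20:80, 1),
                  entry_lag = sample(0:60, 1),
                  infant_status = paste(sample(c("alive", "died", "lost"), k,
                                               TRUE), collapse = "|"),
                  maternal_status = sample(c("alive", "died", "lost"), 1))
  }))

  ne <- sample(5:15, 1)
  raised <- as.Date("2020-01-01") + sample(0:330, ne, replace = TRUE)
  addressed <- runif(ne) < 0.6
  ed <- tibble::tibble(
    edit_id = sprintf("E%03d", seq_len(ne)),
    study_id = sample(ids, ne, replace = TRUE),
    form = sample(c("enrollment", "delivery", "followup"), ne, TRUE),
    field_name = "x", check_type = sample(c("range", "skip"), ne, TRUE),
    severity = sample(c("critical", "noncritical"), ne, TRUE),
    status = ifelse(addressed, "addressed", "open"),
    raised_date = raised,
    resolved_date = dplyr::if_else(addressed,
                                   raised + sample(0:30, ne, replace = TRUE),
                                   as.Date(NA))
  )
  registry_tables(en, dl, bi, fu, ed)
}
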
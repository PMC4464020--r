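# Independent brute-force recomputation of every indicator, written as plain
# per-record loops against the documented definitions. Used as the oracle for
# the engine's vectorised computations; deliberately shares no code with R/.

oracle_site_metrics <- function(reg, as_of, span = 6) {
  w_start <- seq(as.Date(format(as.Date(paste0(as_of, "-01")), "%Y-%m-01")),
                 by = "-1 month", length.out = span)[span]
  months <- seq(w_start, by = "month", length.out = span)
  end_day <- seq(months[span], by = "month", length.out = 2)[2] - 1
  in_months <- function(d) !is.na(d) & as.Date(format(d, "%Y-%m-01")) %in% months
  pctv <- function(num, den) if (den > 0) 100 * num / den else NA_real_

  en <- reg$enrollments; dl <- reg$deliveries
  bi <- reg$births; fu <- reg$followups; ed <- reg$edits
  ddate_of <- function(id) {
    hit <- dl$delivery_date[dl$study_id == id]
    if (length(hit) == 0) as.Date(NA) else hit[1]
  }
  ga_of <- function(id) {
    hit <- dl$gestational_age_weeks[dl$study_id == id]
    if (length(hit) == 0) NA_real_ else hit[1]
  }

  out <- list()

  num <- den <- 0
  for (i in seq_len(nrow(en))) {
    if (in_months(en$enrollment_date[i])) {
      den <- den + 1
      if (isTRUE(en$consent_obtained[i])) num <- num + 1
    }
  }
  out$consent_rate <- pctv(num, den)

  counts <- sapply(months, function(m)
    sum(!is.na(en$enrollment_date) &
          format(en$enrollment_date, "%Y-%m") == format(m, "%Y-%m")))
  out$enroll_variability <- if (span != 6 || min(counts) == 0) NA_real_ else
    max(counts) / min(counts)

  bcounts <- rep(0, length(months))
  for (i in seq_len(nrow(bi))) {
    if (!(bi$status[i] %in% c("live_birth", "stillbirth"))) next
    d <- ddate_of(bi$study_id[i])
    if (is.na(d)) next
    j <- match(format(d, "%Y-%m"), format(months, "%Y-%m"))
    if (!is.na(j)) bcounts[j] <- bcounts[j] + 1
  }
  out$birth_variability <- if (span != 6 || min(bcounts) == 0) NA_real_ else
    max(bcounts) / min(bcounts)

  num <- den <- 0
  for (i in seq_len(nrow(en))) {
    if (!isTRUE(en$consent_obtained[i]) || is.na(en$edd[i])) next
    if (!in_months(en$edd[i])) next
    if (en$edd[i] + 42 > end_day) next
    den <- den + 1
    if (en$study_id[i] %in% dl$study_id) num <- num + 1
  }
  out$delivery_outcome <- pctv(num, den)

  num <- den <- 0
  for (i in seq_len(nrow(dl))) {
    if (!in_months(dl$delivery_date[i])) next
    if (dl$delivery_date[i] + 42 + 21 > end_day) next
    den <- den + 1
    j <- which(fu$study_id == dl$study_id[i])
    if (length(j) == 1) {
      st <- strsplit(fu$infant_status_42d[j], "\\|")[[1]]
      if (!all(st == "lost")) num <- num + 1
    }
  }
  out$followup_outcome <- pctv(num, den)

  males <- females <- 0
  for (i in seq_len(nrow(bi))) {
    if (!(bi$status[i] %in% c("live_birth", "stillbirth"))) next
    if (!in_months(ddate_of(bi$study_id[i]))) next
    if (bi$sex[i] == "male") males <- males + 1
    if (bi$sex[i] == "female") females <- females + 1
  }
  out$sex_ratio <- if (females > 0) males / females else NA_real_

  as_of_m <- as.Date(paste0(as_of, "-01"))
  future <- seq(seq(as_of_m, by = "month", length.out = 2)[2],
                by = "month", length.out = 6)
  hist <- seq(seq(as_of_m, by = "-1 month", length.out = 12)[12],
              by = "month", length.out = 12)
  pipeline <- 0
  for (i in seq_len(nrow(en))) {
    if (!isTRUE(en$consent_obtained[i]) || is.na(en$edd[i])) next
    if (en$study_id[i] %in% dl$study_id) next
    if (as.Date(format(en$edd[i], "%Y-%m-01")) %in% future)
      pipeline <- pipeline + 1
  }
  nhist <- sum(as.Date(format(dl$delivery_date, "%Y-%m-01")) %in% hist)
  out$expected_deliveries <- if (nhist > 0)
    100 * (pipeline / 6) / (nhist / 12) else NA_real_

  out$min_deliveries <- sum(format(dl$delivery_date, "%Y-%m") == as_of)

  sb <- end <- sixwk <- 0
  for (i in seq_len(nrow(bi))) {
    if (!in_months(ddate_of(bi$study_id[i]))) next
    if (bi$status[i] == "stillbirth") sb <- sb + 1
    if (bi$status[i] == "live_birth" && !is.na(bi$death_day_of_life[i])) {
      if (bi$death_day_of_life[i] <= 6) end <- end + 1
      if (bi$death_day_of_life[i] <= 42) sixwk <- sixwk + 1
    }
  }
  out$sb_end_ratio <- if (end > 0) sb / end else NA_real_
  out$end_sixwk_ratio <- if (sixwk > 0) end / sixwk else NA_real_

  num <- den <- 0
  for (i in seq_len(nrow(bi))) {
    if (bi$status[i] != "miscarriage") next
    if (!in_months(ddate_of(bi$study_id[i]))) next
    ga <- ga_of(bi$study_id[i]); wt <- bi$birth_weight_grams[i]
    if (is.na(ga) || is.na(wt)) next
    den <- den + 1
    if (ga < 20 && wt < 500) num <- num + 1
  }
  out$miscarriage_consistency <- pctv(num, den)

  for (cls in c("live", "neonatal_death", "stillbirth")) {
    meas <- anyw <- den <- 0
    for (i in seq_len(nrow(bi))) {
      if (!in_months(ddate_of(bi$study_id[i]))) next
      member <- switch(cls,
        live = bi$status[i] == "live_birth",
        neonatal_death = bi$status[i] == "live_birth" &&
          !is.na(bi$death_day_of_life[i]) && bi$death_day_of_life[i] <= 42,
        stillbirth = bi$status[i] == "stillbirth")
      if (!member) next
      den <- den + 1
      if (bi$birth_weight_source[i] == "measured") meas <- meas + 1
      if (bi$birth_weight_source[i] != "missing") anyw <- anyw + 1
    }
    out[[paste0("bw_measured_", cls)]] <- pctv(meas, den)
    out[[paste0("bw_any_", cls)]] <- pctv(anyw, den)
  }

  num <- den <- 0
  for (i in seq_len(nrow(en))) {
    if (!in_months(en$enrollment_date[i])) next
    den <- den + 1
    if (isTRUE(en$maternal_height_recorded[i]) &&
        isTRUE(en$maternal_weight_recorded[i]) &&
        isTRUE(en$anthropometry_timing_recorded[i])) num <- num + 1
  }
  out$maternal_anthro_complete <- pctv(num, den)

  num <- den <- 0
  for (i in seq_len(nrow(dl))) {
    if (!in_months(dl$delivery_date[i])) next
    st <- bi$status[bi$study_id == dl$study_id[i]]
    if (length(st) > 0 && all(st == "miscarriage")) next
    den <- den + 1
    if (dl$delivery_attendant[i] != "missing" &&
        dl$delivery_location[i] != "missing" &&
        dl$delivery_mode[i] != "missing" &&
        dl$bag_and_mask_used[i] != "missing" &&
        !is.na(dl$gestational_age_weeks[i])) num <- num + 1
  }
  out$delivery_fields_complete <- pctv(num, den)

  gaps <- c(); n7strict <- n7incl <- nelig <- 0
  for (i in seq_len(nrow(bi))) {
    if (!(bi$status[i] %in% c("live_birth", "stillbirth"))) next
    d <- ddate_of(bi$study_id[i])
    if (!in_months(d)) next
    if (is.na(bi$weight_record_date[i]) || bi$birth_weight_source[i] == "missing") next
    g <- as.integer(bi$weight_record_date[i] - d)
    gaps <- c(gaps, g); nelig <- nelig + 1
    if (g < 7) n7strict <- n7strict + 1
    if (g <= 7) n7incl <- n7incl + 1
  }
  out$bw_recording_latency <- if (nelig > 0) median(gaps) else NA_real_
  out$bw_within_7d <- pctv(n7incl, nelig)

  prop_gap <- function(rows, from, to, ok) {
    num <- den <- 0
    for (i in rows) {
      if (is.na(from[i]) || is.na(to[i])) next
      den <- den + 1
      if (ok(as.integer(to[i] - from[i]))) num <- num + 1
    }
    pctv(num, den)
  }
  en_rows <- which(in_months(en$enrollment_date))
  dl_rows <- which(in_months(dl$delivery_date))
  out$enroll_entry_6wk <- prop_gap(en_rows, en$enrollment_date,
                                   en$enrollment_data_entry_date,
                                   function(g) g < 42)
  out$enroll_edd_4wk <- prop_gap(en_rows, en$enrollment_date, en$edd,
                                 function(g) g > 28)
  out$delivery_collection_entry_6wk <- prop_gap(
    dl_rows, dl$delivery_form_completion_date, dl$delivery_data_entry_date,
    function(g) g < 42)
  out$delivery_form_4wk <- prop_gap(dl_rows, dl$delivery_date,
                                    dl$delivery_form_completion_date,
                                    function(g) g < 28)
  out$delivery_form_entry_6wk <- out$delivery_collection_entry_6wk

  num1 <- den1 <- num2 <- den2 <- 0
  for (i in dl_rows) {
    j <- which(fu$study_id == dl$study_id[i])
    if (length(j) != 1) next
    g <- as.integer(fu$followup_form_completion_date[j] - dl$delivery_date[i])
    if (!is.na(g)) {
      den1 <- den1 + 1
      if (g >= 35 && g <= 63) num1 <- num1 + 1
    }
    g2 <- as.integer(fu$followup_data_entry_date[j] -
                       fu$followup_form_completion_date[j])
    if (!is.na(g2)) {
      den2 <- den2 + 1
      if (g2 < 42) num2 <- num2 + 1
    }
  }
  out$followup_form_5_9wk <- pctv(num1, den1)
  out$followup_entry_6wk <- pctv(num2, den2)

  num <- den <- 0
  for (i in seq_len(nrow(ed))) {
    if (ed$severity[i] != "critical") next
    if (!in_months(ed$raised_date[i])) next
    den <- den + 1
    if (ed$status[i] == "addressed") num <- num + 1
  }
  out$critical_edits <- pctv(num, den)

  unlist(out)
}
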
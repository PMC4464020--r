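w6 <- analysis_window("2020-06", 6)
cat29 <- metric_catalogue()

en_batch <- function(n, prefix = "S", cluster = "C01", date = "2020-03-10",
                     edd = "2020-07-15", consent = TRUE) {
  if (n == 0) return(enrollment_prototype_public())
  dplyr::bind_rows(lapply(seq_len(n), function(i)
    make_enrollment(sprintf("%s%04d", prefix, i), cluster_id = cluster,
                    enrollment_date = date, edd = edd, consent = consent)))
}
enrollment_prototype_public <- function() {
  make_enrollment("X", enrollment_date = "2020-01-01", edd = "2020-06-01")[0, ]
}

test_that("consent rate counts consented enrollments in the window", {
  en <- en_batch(100)
  en$consent_obtained[1:3] <- FALSE
  reg <- registry_tables(en)
  r <- consent_rate(reg, w6)
  expect_equal(r$value, 97)
  expect_equal(c(r$numerator, r$denominator), c(97, 100))
  expect_equal(r$flag, "acceptable")

  en$consent_obtained[1:6] <- FALSE
  r <- consent_rate(registry_tables(en), w6)
  expect_equal(r$value, 94)
  expect_equal(r$flag, "out_of_range")

  r0 <- consent_rate(registry_tables(), w6)
  expect_true(is.na(r0$value))
  expect_equal(r0$flag, "insufficient_data")
})

test_that("variability factor is max/min over 6 months, undefined on a zero", {
  expect_equal(variability_factor(rep(30, 6)), 1.0)
  expect_equal(variability_factor(c(40, 30, 35, 28, 32, 38)), 40 / 28)
  expect_true(is.na(variability_factor(c(40, 0, 35, 28, 32, 38))))
  expect_error(variability_factor(c(1, 2, 3)), class = "regqc_bad_value")
})

test_that("delivery outcome denominator honours the EDD grace window", {
  en <- en_batch(100, edd = "2020-03-15")
  dl <- dplyr::bind_rows(lapply(sprintf("S%04d", 1:96), function(id)
    make_delivery(id, delivery_date = "2020-03-20")))
  reg <- registry_tables(en, dl)
  r <- delivery_outcome_proportion(reg, w6)
  expect_equal(r$value, 96)
  expect_equal(r$flag, "acceptable")

  # an EDD whose grace period extends past the window end is not yet expected
  late <- make_enrollment("L001", enrollment_date = "2020-02-01",
                          edd = "2020-06-20")
  r2 <- delivery_outcome_proportion(
    registry_tables(dplyr::bind_rows(en, late), dl), w6)
  expect_equal(r2$denominator, 100)
})

test_that("six-week outcome requires a due delivery and a non-lost status", {
  dates <- rep("2020-02-10", 100)
  en <- en_batch(100, date = "2019-10-01", edd = "2020-02-10")
  dl <- dplyr::bind_rows(lapply(seq_len(100), function(i)
    make_delivery(sprintf("S%04d", i), delivery_date = dates[i])))
  fu <- dplyr::bind_rows(lapply(sprintf("S%04d", 1:97), function(id)
    make_followup(id, "2020-02-10")))
  r <- followup_outcome_proportion(registry_tables(en, dl, followups = fu), w6)
  expect_equal(r$value, 97)

  # all-lost follow-up does not count as an outcome obtained
  fu$infant_status_42d[1] <- "lost"
  r <- followup_outcome_proportion(registry_tables(en, dl, followups = fu), w6)
  expect_equal(r$numerator, 96)

  # a delivery 20 days before the window end is not yet due
  recent <- make_delivery("S0100", delivery_date = "2020-06-10")
  reg <- registry_tables(en, dplyr::bind_rows(dl[-100, ], recent),
                         followups = fu)
  expect_equal(followup_outcome_proportion(reg, w6)$denominator, 99)

  r0 <- followup_outcome_proportion(registry_tables(en, dl), w6)
  expect_equal(r0$value, 0)
})

test_that("sex ratio uses known-sex births and flags the protocol range", {
  en <- en_batch(120, edd = "2020-03-10")
  dl <- dplyr::bind_rows(lapply(sprintf("S%04d", 1:120), function(id)
    make_delivery(id, delivery_date = "2020-03-10")))
  bi <- dplyr::bind_rows(lapply(seq_len(120), function(i)
    make_birth(sprintf("S%04d", i),
               sex = if (i <= 70) "male" else "female",
               delivery_date = "2020-03-10")))
  r <- sex_ratio(registry_tables(en, dl, bi), w6)
  expect_equal(r$value, 1.4)
  expect_equal(r$flag, "out_of_range")

  bi$sex[bi$sex == "female"] <- "missing"
  r <- sex_ratio(registry_tables(en, dl, bi), w6)
  expect_equal(r$flag, "insufficient_data")
})

test_that("expected deliveries compares the EDD pipeline to 12-month history", {
  hist_months <- format(seq(as.Date("2019-07-01"), by = "month",
                            length.out = 12), "%Y-%m-15")
  en_d <- dplyr::bind_rows(lapply(seq_along(hist_months), function(m)
    en_batch(40, prefix = sprintf("H%02d", m), date = "2019-01-01",
             edd = hist_months[m])))
  dl <- dplyr::bind_rows(lapply(en_d$study_id, function(id)
    make_delivery(id, delivery_date = en_d$edd[en_d$study_id == id])))
  pipe_months <- format(seq(as.Date("2020-07-01"), by = "month",
                            length.out = 6), "%Y-%m-10")
  en_p <- dplyr::bind_rows(lapply(seq_along(pipe_months), function(m)
    en_batch(20, prefix = sprintf("P%02d", m), date = "2020-04-01",
             edd = pipe_months[m])))
  reg <- registry_tables(dplyr::bind_rows(en_d, en_p), dl)
  r <- expected_deliveries_ratio(reg, "2020-06")
  expect_equal(r$value, 50)  # 120 EDDs / 6 months vs 40 per month history
  expect_equal(r$flag, "out_of_range")

  r0 <- expected_deliveries_ratio(registry_tables(en_p), "2020-06")
  expect_equal(r0$flag, "insufficient_data")
})

test_that("the monthly delivery minimum is inclusive and a zero is a finding", {
  mk <- function(n) {
    en <- en_batch(max(n, 1), edd = "2020-06-10")
    dl <- if (n > 0) dplyr::bind_rows(lapply(sprintf("S%04d", seq_len(n)),
      function(id) make_delivery(id, delivery_date = "2020-06-10")))
    else make_delivery("S0001", delivery_date = "2020-05-10")  # history only
    registry_tables(en, dl)
  }
  expect_equal(min_deliveries_check(mk(25), "2020-06")$flag, "acceptable")
  expect_equal(min_deliveries_check(mk(24), "2020-06")$flag, "out_of_range")
  r0 <- min_deliveries_check(mk(0), "2020-06")
  expect_equal(r0$value, 0)
  expect_equal(r0$flag, "out_of_range")

  # a unit with no delivery history at all is missing data, not at zero
  rn <- min_deliveries_check(registry_tables(en_batch(1, edd = "2020-06-10")),
                             "2020-06")
  expect_equal(rn$flag, "insufficient_data")
})

test_that("mortality ratios follow the stillbirth/END/6-week definitions", {
  mk <- function(n_sb, n_end, n_late) {
    n <- n_sb + n_end + n_late + 50
    en <- en_batch(n, edd = "2020-03-10")
    dl <- dplyr::bind_rows(lapply(sprintf("S%04d", seq_len(n)), function(id)
      make_delivery(id, delivery_date = "2020-03-10")))
    status <- c(rep("stillbirth", n_sb), rep("live_birth", n - n_sb))
    death <- c(rep(NA, n_sb), rep(3L, n_end), rep(20L, n_late),
               rep(NA, n - n_sb - n_end - n_late))
    bi <- dplyr::bind_rows(lapply(seq_len(n), function(i)
      make_birth(sprintf("S%04d", i), status = status[i],
                 death_day = death[i], delivery_date = "2020-03-10")))
    registry_tables(en, dl, bi)
  }
  r <- mortality_ratios(mk(10, 10, 0), w6)
  expect_equal(r$value[r$metric_id == "sb_end_ratio"], 1.0)
  expect_equal(r$flag[r$metric_id == "sb_end_ratio"], "acceptable")

  r <- mortality_ratios(mk(30, 10, 0), w6)
  expect_equal(r$value[r$metric_id == "sb_end_ratio"], 3.0)
  expect_equal(r$flag[r$metric_id == "sb_end_ratio"], "out_of_range")

  r <- mortality_ratios(mk(5, 8, 2), w6)
  expect_equal(r$value[r$metric_id == "end_sixwk_ratio"], 0.8)
  expect_equal(r$flag[r$metric_id == "end_sixwk_ratio"], "acceptable")

  r <- mortality_ratios(mk(5, 0, 0), w6)
  expect_equal(r$flag[r$metric_id == "sb_end_ratio"], "insufficient_data")
})

test_that("miscarriage consistency applies the <20 weeks / <500 g rule", {
  expect_equal(classify_miscarriage(19, 450), "consistent")
  expect_equal(classify_miscarriage(22, 450), "inconsistent")
  expect_equal(classify_miscarriage(19, 600), "inconsistent")
  expect_equal(classify_miscarriage(NA, 450), "unassessable")

  en <- en_batch(3, edd = "2020-03-10")
  dl <- dplyr::bind_rows(
    make_delivery("S0001", delivery_date = "2020-03-10", ga = 19,
                  mode = "missing", bag_mask = "missing"),
    make_delivery("S0002", delivery_date = "2020-03-10", ga = 22,
                  mode = "missing", bag_mask = "missing"),
    make_delivery("S0003", delivery_date = "2020-03-10", ga = NA,
                  mode = "missing", bag_mask = "missing"))
  bi <- dplyr::bind_rows(lapply(1:3, function(i)
    make_birth(sprintf("S%04d", i), status = "miscarriage", sex = "missing",
               weight = 450, delivery_date = "2020-03-10")))
  r <- miscarriage_consistency(registry_tables(en, dl, bi), w6)
  expect_equal(c(r$numerator, r$denominator), c(1, 2))
  expect_equal(r$value, 50)
})

test_that("birth-weight metrics stratify by outcome and partition by source", {
  en <- en_batch(100, edd = "2020-03-10")
  dl <- dplyr::bind_rows(lapply(sprintf("S%04d", 1:100), function(id)
    make_delivery(id, delivery_date = "2020-03-10")))
  src <- c(rep("measured", 80), rep("estimated", 15), rep("missing", 5))
  bi <- dplyr::bind_rows(lapply(seq_len(100), function(i)
    make_birth(sprintf("S%04d", i),
               weight = if (src[i] == "missing") NA else 3000,
               source = src[i], delivery_date = "2020-03-10")))
  r <- birthweight_metrics(registry_tables(en, dl, bi), w6)
  expect_equal(r$value[r$metric_id == "bw_measured_live"], 80)
  expect_equal(r$flag[r$metric_id == "bw_measured_live"], "out_of_range")
  expect_equal(r$value[r$metric_id == "bw_any_live"], 95)
  bk <- attr(r, "breakdown")
  expect_equal(bk$pct, c(80, 15, 5))
  expect_equal(sum(bk$pct), 100)
})

test_that("key-field completeness is conjunctive and inclusive at the bound", {
  en <- en_batch(100, edd = "2020-07-15")
  en$maternal_weight_recorded[1] <- FALSE  # height present, weight missing
  dl <- dplyr::bind_rows(lapply(sprintf("S%04d", 1:100), function(id)
    make_delivery(id, delivery_date = "2020-03-10")))
  dl$bag_and_mask_used[1] <- "missing"
  bi <- dplyr::bind_rows(lapply(sprintf("S%04d", 1:100), function(id)
    make_birth(id, delivery_date = "2020-03-10")))
  r <- key_field_completeness(registry_tables(en, dl, bi), w6)
  expect_equal(r$value[r$metric_id == "maternal_anthro_complete"], 99)
  expect_equal(r$value[r$metric_id == "delivery_fields_complete"], 99)
  expect_equal(r$flag[r$metric_id == "delivery_fields_complete"], "acceptable")
})

test_that("day-gap compliance uses the printed strict operators", {
  en <- en_batch(10, edd = "2020-07-15")
  dl <- dplyr::bind_rows(lapply(seq_len(10), function(i)
    make_delivery(sprintf("S%04d", i), delivery_date = "2020-03-10",
                  completion_lag = if (i == 1) 28L else 0L)))
  r <- process_timeliness(registry_tables(en, dl), w6)
  ff <- r[r$metric_id == "delivery_form_4wk", ]
  expect_equal(ff$numerator, 9)  # the 28-day gap fails "< 4 weeks"
  expect_equal(ff$value, 90)
  expect_equal(ff$flag, "acceptable")  # 90 meets the >90% bound inclusively
})

test_that("records with missing dates leave the denominator and are tallied", {
  en <- en_batch(10, edd = "2020-07-15")
  en$enrollment_data_entry_date[1:2] <- as.Date(NA)
  r <- process_timeliness(registry_tables(en), w6)
  ee <- r[r$metric_id == "enroll_entry_6wk", ]
  expect_equal(ee$denominator, 8)
  tally <- attr(r, "missing_dates")
  expect_equal(tally$n_missing_dates[tally$metric_id == "enroll_entry_6wk"], 2)
})

test_that("critical-edit resolution is a windowed proportion", {
  mk <- function(n_addr, n_open) {
    n <- n_addr + n_open
    tibble::tibble(
      edit_id = sprintf("E%02d", seq_len(n)), study_id = "S0001",
      form = "delivery", field_name = "x", check_type = "range",
      severity = "critical",
      status = c(rep("addressed", n_addr), rep("open", n_open)),
      raised_date = as.Date("2020-03-15"),
      resolved_date = c(rep(as.Date("2020-03-20"), n_addr),
                        rep(as.Date(NA), n_open)))
  }
  en <- en_batch(1, edd = "2020-07-15")
  r <- critical_edits_addressed(registry_tables(en, edits = mk(9, 1)), w6)
  expect_equal(r$value, 90)
  expect_equal(r$flag, "acceptable")
  r <- critical_edits_addressed(registry_tables(en, edits = mk(7, 3)), w6)
  expect_equal(r$value, 70)
  expect_equal(r$flag, "out_of_range")
  r <- critical_edits_addressed(registry_tables(en), w6)
  expect_equal(r$flag, "insufficient_data")
})

test_that("proportions stay in [0,100] and site values pool cluster counts", {
  for (seed in c(3, 4, 5)) {
    reg <- random_fixture(seed)
    m <- compute_metrics(reg, "2020-10")
    pr <- m[!is.na(m$value) &
              m$metric_id %in% cat29$metric_id[cat29$units == "proportion_pct"], ]
    expect_true(all(pr$value >= 0 & pr$value <= 100))
    expect_true(all(pr$numerator <= pr$denominator))
    vr <- m$value[grepl("variability", m$metric_id) & !is.na(m$value)]
    expect_true(all(vr >= 1))

    site <- m[m$scope == "site", ]
    clus <- m[m$scope == "cluster", ]
    for (id in c("consent_rate", "maternal_anthro_complete", "sex_ratio")) {
      s <- site[site$metric_id == id, ]
      cl <- clus[clus$metric_id == id, ]
      expect_equal(s$numerator, sum(cl$numerator), info = id)
      expect_equal(s$denominator, sum(cl$denominator), info = id)
    }
  }
})

test_that("monthly denominators partition the span denominator", {
  reg <- random_fixture(21)
  whole <- consent_rate(reg, analysis_window("2020-12", 12))
  parts <- sapply(0:11, function(k) {
    m <- format(seq(as.Date("2020-12-01"), by = "-1 month",
                    length.out = 12)[k + 1], "%Y-%m")
    consent_rate(reg, analysis_window(m, 1))$denominator
  })
  expect_equal(sum(parts), whole$denominator)
})
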
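test_that("a defect-free simulated extract raises no edit items", {
  reg <- simulate_registry(simulation_config(n_clusters = 3, months = 12,
                                             seed = 23))
  expect_equal(nrow(run_checks(reg)), 0)
})

test_that("range rules flag out-of-range values on the right record", {
  en <- make_enrollment("S01", enrollment_date = "2020-01-05",
                        edd = "2020-06-01")
  dl <- make_delivery("S01", delivery_date = "2020-06-01", ga = 39)
  bi <- make_birth("S01", weight = 7000, delivery_date = "2020-06-01")
  ed <- run_checks(registry_tables(en, dl, bi))
  expect_equal(nrow(ed), 1)
  expect_equal(ed$check_type, "range")
  expect_equal(ed$study_id, "S01")
  expect_equal(ed$field_name, "birth_weight_grams")
  expect_equal(ed$severity, "noncritical")

  dl$gestational_age_weeks <- 50
  ed <- run_checks(registry_tables(en, dl, bi))
  expect_setequal(ed$field_name,
                  c("birth_weight_grams", "gestational_age_weeks"))
})

test_that("an overdue EDD with no delivery form is a critical edit", {
  en <- dplyr::bind_rows(
    make_enrollment("S01", enrollment_date = "2020-01-05", edd = "2020-06-01"),
    make_enrollment("S02", enrollment_date = "2020-01-05", edd = "2020-07-20"))
  dl <- make_delivery("S03", delivery_date = "2020-07-31")
  en3 <- make_enrollment("S03", enrollment_date = "2020-01-05",
                         edd = "2020-07-25")
  reg <- registry_tables(dplyr::bind_rows(en, en3), dl)
  ed <- run_checks(reg, as_of = as.Date("2020-07-31"))
  # S01's EDD is 60 days past; S02's grace has not elapsed; S03 delivered
  miss <- ed[ed$check_type == "missing_expected_form" & ed$form == "delivery", ]
  expect_equal(miss$study_id, "S01")
  expect_equal(miss$severity, "critical")
  # S03 delivered 0 days ago: no follow-up expected yet
  expect_equal(sum(ed$form == "followup"), 0)
})

test_that("an old delivery with no follow-up form is a critical edit", {
  en <- make_enrollment("S01", enrollment_date = "2020-01-05",
                        edd = "2020-04-01")
  dl <- make_delivery("S01", delivery_date = "2020-04-01")
  ed <- run_checks(registry_tables(en, dl), as_of = as.Date("2020-07-01"))
  expect_equal(ed$edit_id, "missing_followup_form:S01")
})

test_that("skip and cross-form rules fire on inconsistent records", {
  en <- make_enrollment("S01", enrollment_date = "2020-01-05",
                        edd = "2020-04-01", consent = FALSE)
  dl <- make_delivery("S01", delivery_date = "2020-04-01", ga = 18,
                      bag_mask = "yes")
  bi <- make_birth("S01", status = "miscarriage", sex = "missing",
                   weight = 800, delivery_date = "2020-04-01")
  ed <- run_checks(registry_tables(en, dl, bi),
                   as_of = as.Date("2020-04-15"))
  expect_setequal(
    sub(":.*", "", ed$edit_id),
    c("bag_mask_miscarriage", "delivery_without_consent",
      "miscarriage_inconsistent"))
  expect_equal(ed$severity[grepl("miscarriage_inconsistent", ed$edit_id)],
               "critical")
})

test_that("a stillbirth carrying a day of death is caught", {
  en <- make_enrollment("S01", enrollment_date = "2020-01-05",
                        edd = "2020-04-01")
  dl <- make_delivery("S01", delivery_date = "2020-04-01")
  bi <- make_birth("S01", status = "stillbirth", death_day = 2L,
                   delivery_date = "2020-04-01")
  reg <- registry_tables(en, dl, bi, validate = FALSE)
  ed <- run_checks(reg, as_of = as.Date("2020-04-15"))
  expect_true("stillbirth_death_day:S01#1" %in% ed$edit_id)
})

test_that("the check engine is pure with stable ordering", {
  reg <- random_fixture(41)
  a <- run_checks(reg, as_of = as.Date("2020-12-31"))
  b <- run_checks(reg, as_of = as.Date("2020-12-31"))
  expect_identical(a, b)
  expect_false(is.unsorted(a$study_id))
})

test_that("every checked-field defect at rate 1 triggers edit items", {
  reg <- simulate_registry(simulation_config(n_clusters = 2, months = 10,
                                             seed = 29))
  for (d in c("drop_followup_record", "drop_consent_flag")) {
    args <- setNames(list(1), d)
    out <- inject_defects(reg, do.call(defect_config, args), seed = 2)
    expect_gt(nrow(run_checks(out)), 0, label = d)
  }
})

test_that("resolving edits is tracked and idempotent", {
  reg <- random_fixture(41)
  ed <- run_checks(reg, as_of = as.Date("2020-12-31"))
  expect_gt(nrow(ed), 0)
  ed2 <- resolve_edits(ed, ed$edit_id[1], resolved_date = "2021-01-10")
  expect_equal(ed2$status[1], "addressed")
  expect_equal(ed2$resolved_date[1], as.Date("2021-01-10"))
  ed3 <- resolve_edits(ed2, ed$edit_id[1], resolved_date = "2021-05-05")
  expect_identical(ed3, ed2)
  expect_error(resolve_edits(ed, "no-such-edit"),
               class = "regqc_unknown_edit")
})

test_that("custom rule files round-trip and unknown rules are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  rules <- default_check_rules()
  rules$upper[rules$rule_id == "bw_range"] <- 6000
  write_check_rules(rules, path)
  back <- read_check_rules(path)
  expect_equal(back, rules)

  en <- make_enrollment("S01", enrollment_date = "2020-01-05",
                        edd = "2020-06-01")
  dl <- make_delivery("S01", delivery_date = "2020-06-01")
  bi <- make_birth("S01", weight = 6200, delivery_date = "2020-06-01")
  reg <- registry_tables(en, dl, bi)
  expect_equal(nrow(run_checks(reg)), 0)       # default bound 6500
  expect_equal(nrow(run_checks(reg, back)), 1) # tightened bound 6000

  rules$rule_id[1] <- "made_up"
  write_check_rules(rules, path)
  expect_error(read_check_rules(path), class = "regqc_bad_config")
})
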
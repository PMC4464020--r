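#' Simulator configuration
#'
#' Parameters of the synthetic multi-cluster registry. Defaults describe a
#' well-run registry: 300-500 births per cluster per year with mild seasonal
#' variation, mortality probabilities placed comfortably inside the
#' monitoring ranges, and form/data-entry latencies whose distributions sit
#' well inside the process windows, so that a defect-free simulation is a
#' known-good baseline for every indicator. The mortality probabilities are
#' documented placeholders for a generic low-resource setting, not estimates
#' for any particular registry site.
#'
#' Latency distributions are log-normal, given as `list(meanlog, sdlog)` in
#' days.
#'
#' @param n_clusters Number of clusters.
#' @param births_per_cluster_year Length-2 range; each cluster's annual birth
#'   rate is drawn uniformly from it.
#' @param months Simulated calendar span in months.
#' @param start_month First simulated month (`"YYYY-MM"` or Date).
#' @param seasonality_amplitude Sinusoidal amplitude of the monthly birth
#'   rate, in \[0, 1).
#' @param p_stillbirth,p_early_neonatal_death,p_late_neonatal_death
#'   Per-infant probabilities (early: death on day 0-6; late: day 7-42).
#' @param p_miscarriage Per-pregnancy probability the pregnancy ends in
#'   miscarriage.
#' @param p_maternal_death Probability the mother has died by the six-week
#'   visit.
#' @param p_male Probability an infant is male.
#' @param p_twin Probability of a twin pregnancy.
#' @param enrollment_lead Log-normal distribution of days between enrollment
#'   and the EDD.
#' @param latency_delivery_form Delivery to delivery-form completion.
#' @param latency_data_entry Form completion to data entry (all forms).
#' @param latency_weight Birth to weight measurement.
#' @param latency_followup_form Delivery to follow-up form completion.
#' @param seed Integer seed; the simulation is a pure function of the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_clusters = 10,
                              births_per_cluster_year = c(300, 500),
                              months = 24,
                              start_month = "2020-01",
                              seasonality_amplitude = 0.10,
                              p_stillbirth = 0.030,
                              p_early_neonatal_death = 0.024,
                              p_late_neonatal_death = 0.008,
                              p_miscarriage = 0.020,
                              p_maternal_death = 0.002,
                              p_male = 0.515,
                              p_twin = 0.015,
                              enrollment_lead = list(meanlog = log(150),
                                                     sdlog = 0.20),
                              latency_delivery_form = list(meanlog = log(5),
                                                           sdlog = 0.6),
                              latency_data_entry = list(meanlog = log(7),
                                                        sdlog = 0.6),
                              latency_weight = list(meanlog = log(1.5),
                                                    sdlog = 0.5),
                              latency_followup_form = list(meanlog = log(45),
                                                           sdlog = 0.08),
                              seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_stillbirth, cfg$p_early_neonatal_death,
             cfg$p_late_neonatal_death, cfg$p_miscarriage,
             cfg$p_maternal_death, cfg$p_male, cfg$p_twin)
  if (any(probs < 0 | probs > 1))
    abort_regqc("probabilities must lie in [0, 1]", "regqc_bad_config")
  if (cfg$p_stillbirth + cfg$p_miscarriage > 1)
    abort_regqc("p_stillbirth + p_miscarriage must not exceed 1",
                "regqc_bad_config")
  if (cfg$p_early_neonatal_death + cfg$p_late_neonatal_death > 1)
    abort_regqc("neonatal death probabilities must sum to at most 1",
                "regqc_bad_config")
  if (length(cfg$births_per_cluster_year) != 2 ||
      diff(cfg$births_per_cluster_year) < 0 ||
      min(cfg$births_per_cluster_year) <= 0)
    abort_regqc("births_per_cluster_year must be a non-empty positive range",
                "regqc_bad_config")
  if (cfg$months < 1 || cfg$n_clusters < 1)
    abort_regqc("need at least one month and one cluster", "regqc_bad_config")
  if (cfg$seasonality_amplitude < 0 || cfg$seasonality_amplitude >= 1)
    abort_regqc("seasonality_amplitude must lie in [0, 1)", "regqc_bad_config")
  cfg$start_month <- as_month(cfg$start_month)
  class(cfg) <- "simulation_config"
  cfg
}

rlnorm_days <- function(n, dist) {
  round(rlnorm(n, meanlog = dist$meanlog, sdlog = dist$sdlog))
}

#' Simulate a multi-cluster registry
#'
#' Generates a linked registry extract from a [simulation_config()]. Monthly
#' birth counts per cluster follow an inhomogeneous Poisson process with a
#' shared sinusoidal seasonal component; infant outcomes, sexes and all form
#' and data-entry latencies are drawn per the configured probabilities and
#' distributions. Pregnancies due shortly *after* the simulated span appear
#' as enrollment-only rows (the enrollment pipeline), so the
#' expected-deliveries indicator has a realistic numerator at the end of the
#' span. The output is deterministic given the seed and satisfies every
#' record-model invariant; the seed and config are recorded in the
#' `sim_meta` attribute.
#'
#' @param config A [simulation_config()].
#' @return A validated [registry_tables()] extract.
#' @export
simulate_registry <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  span_end <- month_add(cfg$start_month, cfg$months) - 1L
  horizon <- cfg$months + 7L  # extra months feed the enrollment pipeline
  annual <- runif(cfg$n_clusters, cfg$births_per_cluster_year[1],
                  cfg$births_per_cluster_year[2])

  en <- list(); dl <- list(); bi <- list(); fu <- list()
  for (cl in seq_len(cfg$n_clusters)) {
    cluster_id <- sprintf("C%02d", cl)
    counter <- 0L
    for (m in seq_len(horizon)) {
      mstart <- month_add(cfg$start_month, m - 1L)
      mdays <- as.integer(month_add(mstart, 1L) - mstart)
      rate <- annual[cl] / 12 *
        (1 + cfg$seasonality_amplitude * sin(2 * pi * (m - 1) / 12))
      n <- rpois(1, rate)
      if (n == 0) next
      ids <- sprintf("%s-%05d", cluster_id, counter + seq_len(n))
      counter <- counter + n

      delivery_date <- mstart + sample.int(mdays, n, replace = TRUE) - 1L
      edd_jitter <- pmin(pmax(round(rnorm(n, 0, 7)), -21L), 21L)
      edd <- delivery_date - edd_jitter
      lead <- pmax(rlnorm_days(n, cfg$enrollment_lead), 30L)
      enrollment_date <- edd - lead
      enroll_completion <- enrollment_date + sample(0:2, n, replace = TRUE)
      enroll_entry <- enroll_completion + rlnorm_days(n, cfg$latency_data_entry)

      is_misc <- runif(n) < cfg$p_miscarriage
      delivered <- delivery_date <= span_end

      en[[length(en) + 1]] <- tibble::tibble(
        study_id = ids, cluster_id = cluster_id,
        consent_obtained = TRUE,
        enrollment_date = enrollment_date, edd = edd,
        maternal_height_recorded = TRUE, maternal_weight_recorded = TRUE,
        anthropometry_timing_recorded = TRUE,
        enrollment_form_completion_date = enroll_completion,
        enrollment_data_entry_date = enroll_entry,
        .delivered = delivered, .enrolled_in_span = enrollment_date <= span_end
      )
      if (!any(delivered)) next

      keep <- which(delivered)
      nk <- length(keep)
      misc_k <- is_misc[keep]
      ga <- ifelse(misc_k, round(runif(nk, 8, 19.5), 1),
                   round(pmin(pmax(rnorm(nk, 39, 2), 30), 44), 1))
      form_completion <- delivery_date[keep] +
        rlnorm_days(nk, cfg$latency_delivery_form)
      entry <- form_completion + rlnorm_days(nk, cfg$latency_data_entry)
      dl[[length(dl) + 1]] <- tibble::tibble(
        study_id = ids[keep], cluster_id = cluster_id,
        delivery_date = delivery_date[keep],
        delivery_location = sample(c("home", "health_center", "hospital"),
                                   nk, replace = TRUE, prob = c(.3, .4, .3)),
        delivery_attendant = sample(c("physician", "nurse_midwife", "TBA",
                                      "family"), nk, replace = TRUE,
                                    prob = c(.2, .4, .3, .1)),
        delivery_mode = ifelse(misc_k, "missing",
                               sample(c("vaginal", "cesarean"), nk,
                                      replace = TRUE, prob = c(.88, .12))),
        bag_and_mask_used = ifelse(misc_k, "missing",
                                   sample(c("yes", "no"), nk, replace = TRUE,
                                          prob = c(.05, .95))),
        gestational_age_weeks = ga,
        delivery_form_completion_date = form_completion,
        delivery_data_entry_date = entry
      )

      # infants
      n_infants <- ifelse(misc_k, 1L, 1L + (runif(nk) < cfg$p_twin))
      idx <- rep(seq_len(nk), n_infants)
      infant_index <- unlist(lapply(n_infants, seq_len), use.names = FALSE)
      ni <- length(idx)
      misc_i <- misc_k[idx]
      p_sb_cond <- cfg$p_stillbirth / (1 - cfg$p_miscarriage)
      sb <- !misc_i & runif(ni) < p_sb_cond
      status <- ifelse(misc_i, "miscarriage",
                       ifelse(sb, "stillbirth", "live_birth"))
      u <- runif(ni)
      death_day <- ifelse(
        status == "live_birth" & u < cfg$p_early_neonatal_death,
        sample(0:6, ni, replace = TRUE),
        ifelse(status == "live_birth" &
                 u < cfg$p_early_neonatal_death + cfg$p_late_neonatal_death,
               sample(7:42, ni, replace = TRUE), NA_integer_))
      weight <- ifelse(misc_i, round(runif(ni, 210, 460)),
                       ifelse(status == "stillbirth",
                              round(pmin(pmax(rnorm(ni, 2600, 600), 600), 5000)),
                              round(pmin(pmax(rnorm(ni, 3000, 450), 600), 5400))))
      wdate <- delivery_date[keep][idx] + rlnorm_days(ni, cfg$latency_weight)
      bi[[length(bi) + 1]] <- tibble::tibble(
        study_id = ids[keep][idx], infant_index = as.integer(infant_index),
        status = status,
        sex = ifelse(misc_i, "missing",
                     ifelse(runif(ni) < cfg$p_male, "male", "female")),
        birth_weight_grams = as.numeric(weight),
        birth_weight_source = "measured",
        weight_record_date = wdate,
        death_day_of_life = as.integer(death_day)
      )

      fu_completion <- delivery_date[keep] +
        pmin(pmax(rlnorm_days(nk, cfg$latency_followup_form), 35L), 63L)
      fu_entry <- fu_completion + rlnorm_days(nk, cfg$latency_data_entry)
      inf_status <- vapply(seq_len(nk), function(i) {
        sel <- idx == i
        st <- ifelse(status[sel] != "live_birth" | !is.na(death_day[sel]),
                     "died", "alive")
        paste(st, collapse = "|")
      }, character(1))
      fu[[length(fu) + 1]] <- tibble::tibble(
        study_id = ids[keep],
        followup_form_completion_date = fu_completion,
        followup_data_entry_date = fu_entry,
        infant_status_42d = inf_status,
        maternal_status_42d = ifelse(runif(nk) < cfg$p_maternal_death,
                                     "died", "alive")
      )
    }
  }
  en <- dplyr::bind_rows(en)
  # pipeline pregnancies appear only if enrolled within the span; delivered
  # pregnancies always appear (their enrollment predates their delivery)
  en <- en[en$.delivered | en$.enrolled_in_span, ]
  en$.delivered <- NULL
  en$.enrolled_in_span <- NULL

  reg <- registry_tables(
    enrollments = en,
    deliveries = dplyr::bind_rows(c(list(delivery_prototype()), dl)),
    births = dplyr::bind_rows(c(list(birth_prototype()), bi)),
    followups = dplyr::bind_rows(c(list(followup_prototype()), fu))
  )
  attr(reg, "sim_meta") <- list(seed = cfg$seed, config = unclass(cfg),
                                span_end = span_end)
  reg
}
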
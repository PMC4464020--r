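#' Assemble a monitoring report
#'
#' Builds the monthly monitoring report for one scope unit (a cluster or the
#' pooled site): the full indicator battery for the report month, a
#' trailing six-month moving-average series per indicator (each point is the
#' indicator recomputed over the six-month window ending at that month), a
#' flag summary, an edit summary, and the figure-style trend tables used in
#' site review meetings:
#'
#' * `delivery_outcome_by_year` — expected-delivery-outcome percent per
#'   calendar year of the data span.
#' * `births_by_cluster_month` — monthly live + stillborn birth counts per
#'   cluster over the trailing six months.
#' * `sb_end_categories` — proportion of clusters whose trailing-12-month
#'   stillbirth : early-neonatal-death ratio falls in each category
#'   (`<0.5`, `0.5-2.0`, `>2.0`; undefined ratios tallied separately).
#' * `bw_source_breakdown` — measured / estimated / missing birth-weight
#'   shares over the report window.
#' * `delivery_form_timeliness` — percent of delivery forms completed within
#'   4 weeks, per month over the trailing twelve months.
#'
#' @param reg A [registry_tables()] extract.
#' @param month Report month (`Date` or `"YYYY-MM"`); must lie inside the
#'   data span.
#' @param scope `"cluster"` or `"site"`.
#' @param scope_id Cluster id (required for cluster scope).
#' @param catalogue Indicator catalogue.
#' @param edits Optional edit-item tibble; defaults to `reg$edits`.
#' @param span_months Rolling window length (6 monthly, 3 for a quarterly
#'   roll-up of the trailing quarter; the moving-average series always uses
#'   6).
#' @return A `monitoring_report` list.
#' @export
build_report <- function(reg, month, scope = c("site", "cluster"),
                         scope_id = NULL, catalogue = metric_catalogue(),
                         edits = NULL, span_months = 6) {
  scope <- match.arg(scope)
  month <- as_month(month)
  if (!is.null(edits)) reg$edits <- coerce_table(edits, edit_prototype(), "edits")

  span <- range(c(reg$enrollments$enrollment_date, reg$deliveries$delivery_date),
                na.rm = TRUE)
  if (month < month_floor(span[1]) || month > month_floor(span[2]))
    abort_regqc(sprintf("report month %s outside data span %s..%s",
                        format(month, "%Y-%m"), format(span[1], "%Y-%m"),
                        format(span[2], "%Y-%m")),
                "regqc_bad_month")

  if (scope == "cluster") {
    if (is.null(scope_id))
      abort_regqc("cluster scope needs a scope_id", "regqc_bad_value")
    unit <- filter_cluster(reg, scope_id)
  } else {
    scope_id <- scope_id %||% "site"
    unit <- reg
  }

  metrics <- compute_metrics(unit, month, catalogue, scope = if (scope == "site") "site" else "cluster",
                             span_months = span_months, site_id = scope_id)
  if (scope == "cluster") metrics <- metrics[metrics$scope_id == scope_id, ]

  ma <- dplyr::bind_rows(lapply(0:5, function(k) {
    m <- month_add(month, -k)
    if (m < month_floor(span[1])) return(NULL)
    res <- compute_metrics(unit, m, catalogue,
                           scope = if (scope == "site") "site" else "cluster",
                           span_months = 6, site_id = scope_id)
    tibble::tibble(metric_id = res$metric_id, month = m, value = res$value)
  }))
  ma <- ma[order(ma$metric_id, ma$month), ]

  flag_summary <- dplyr::count(metrics, .data$flag, name = "n")
  ed <- reg$edits
  if (scope == "cluster") ed <- unit$edits
  edit_summary <- dplyr::count(ed, .data$severity, .data$status, name = "n")

  series <- list(
    delivery_outcome_by_year = delivery_outcome_by_year(unit, catalogue),
    births_by_cluster_month = births_by_cluster_month(reg, analysis_window(month, 6)),
    sb_end_categories = sb_end_categories(reg, month, catalogue),
    bw_source_breakdown = attr(
      birthweight_metrics(unit, analysis_window(month, span_months), catalogue),
      "breakdown"),
    delivery_form_timeliness = delivery_form_timeliness_series(unit, month,
                                                               catalogue)
  )

  out <- list(scope = scope, scope_id = scope_id, report_month = month,
              span_months = span_months, metrics = metrics,
              moving_average = ma, flag_summary = flag_summary,
              edit_summary = edit_summary, series = series)
  class(out) <- "monitoring_report"
  out
}

delivery_outcome_by_year <- function(unit, catalogue) {
  dates <- c(unit$enrollments$edd, unit$deliveries$delivery_date)
  yrs <- sort(unique(as.integer(format(dates[!is.na(dates)], "%Y"))))
  dplyr::bind_rows(lapply(yrs, function(y) {
    w <- analysis_window(as.Date(sprintf("%d-12-01", y)), 12)
    r <- delivery_outcome_proportion(unit, w, catalogue)
    tibble::tibble(year = y, numerator = r$numerator,
                   denominator = r$denominator, value = r$value)
  }))
}

births_by_cluster_month <- function(reg, window) {
  bd <- births_dated(reg)
  bd <- bd[bd$status %in% c("live_birth", "stillbirth") &
             month_floor(bd$delivery_date) %in% window$months, ]
  grid <- tidyr::expand_grid(
    cluster_id = sort(unique(reg$enrollments$cluster_id)),
    month = window$months)
  counts <- dplyr::count(
    tibble::tibble(cluster_id = bd$cluster_id,
                   month = month_floor(bd$delivery_date)),
    .data$cluster_id, .data$month, name = "births")
  out <- dplyr::left_join(grid, counts, by = c("cluster_id", "month"))
  out$births <- out$births %|na|% 0L
  out
}

sb_end_categories <- function(reg, month, catalogue) {
  w <- analysis_window(month, 12)
  clusters <- sort(unique(reg$enrollments$cluster_id))
  vals <- vapply(clusters, function(cl) {
    mortality_ratios(filter_cluster(reg, cl), w, catalogue)$value[1]
  }, numeric(1))
  defined <- vals[!is.na(vals)]
  n <- length(defined)
  tibble::tibble(
    category = c("<0.5", "0.5-2.0", ">2.0", "undefined"),
    n_clusters = c(sum(defined < 0.5), sum(defined >= 0.5 & defined <= 2.0),
                   sum(defined > 2.0), sum(is.na(vals))),
    proportion = c(if (n > 0) c(sum(defined < 0.5),
                                sum(defined >= 0.5 & defined <= 2.0),
                                sum(defined > 2.0)) / n else rep(NA_real_, 3),
                   NA_real_)
  )
}

delivery_form_timeliness_series <- function(unit, month, catalogue) {
  months <- month_seq(month_add(month, -11L), month)
  dplyr::bind_rows(lapply(months, function(m) {
    w <- analysis_window(m, 1)
    r <- process_timeliness(unit, w, catalogue)
    r <- r[r$metric_id == "delivery_form_4wk", ]
    tibble::tibble(month = m, numerator = r$numerator,
                   denominator = r$denominator, value = r$value)
  }))
}

#' @export
print.monitoring_report <- function(x, ...) {
  cat(sprintf("<monitoring_report> %s %s, month %s\n", x$scope, x$scope_id,
              format(x$report_month, "%Y-%m")))
  fs <- setNames(x$flag_summary$n, x$flag_summary$flag)
  cat(sprintf("  indicators: %d (%d acceptable, %d out of range, %d insufficient)\n",
              nrow(x$metrics), fs["acceptable"] %|na|% 0,
              fs["out_of_range"] %|na|% 0, fs["insufficient_data"] %|na|% 0))
  oor <- x$metrics[x$metrics$flag == "out_of_range", ]
  if (nrow(oor) > 0)
    cat("  out of range:", paste(oor$metric_id, collapse = ", "), "\n")
  invisible(x)
}

#' Draw the monthly re-keying sample
#'
#' Returns, per cluster, a seeded uniform random sample of the forms whose
#' data entry fell in the given month, of size `ceiling(fraction * n)` —
#' the sampling list handed to double-data-entry staff. The protocol floor
#' is 5%; a lower fraction is an error unless `allow_below_minimum` is set,
#' in which case a warning is raised.
#'
#' @param reg A [registry_tables()] extract.
#' @param month Calendar month of data entry.
#' @param fraction Sampling fraction (default 0.05).
#' @param seed Integer seed; the list is reproducible given the seed.
#' @param allow_below_minimum Permit fractions below 0.05 (with a warning).
#' @return Tibble `cluster_id`, `form`, `study_id`, ordered for dispatch.
#' @export
rekey_sample <- function(reg, month, fraction = 0.05, seed = 1L,
                         allow_below_minimum = FALSE) {
  if (fraction < 0.05) {
    if (!allow_below_minimum)
      abort_regqc("re-keying fraction below the 5% protocol minimum",
                  "regqc_bad_value")
    warning("re-keying fraction below the 5% protocol minimum")
  }
  month <- as_month(month)
  cl <- reg$enrollments[, c("study_id", "cluster_id")]
  forms <- dplyr::bind_rows(
    tibble::tibble(form = "enrollment", study_id = reg$enrollments$study_id,
                   entry = reg$enrollments$enrollment_data_entry_date),
    tibble::tibble(form = "delivery", study_id = reg$deliveries$study_id,
                   entry = reg$deliveries$delivery_data_entry_date),
    tibble::tibble(form = "followup", study_id = reg$followups$study_id,
                   entry = reg$followups$followup_data_entry_date)
  )
  forms <- forms[!is.na(forms$entry) & month_floor(forms$entry) == month, ]
  forms <- dplyr::inner_join(forms, cl, by = "study_id")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  out <- dplyr::bind_rows(lapply(sort(unique(forms$cluster_id)), function(cid) {
    f <- forms[forms$cluster_id == cid, ]
    f <- f[order(f$form, f$study_id), ]
    k <- ceiling(fraction * nrow(f))
    f[sort(sample.int(nrow(f), k)), c("cluster_id", "form", "study_id")]
  }))
  out
}

#' Export a monitoring report as delimited text
#'
#' Writes `metrics.csv`, `moving_average.csv`, `flag_summary.csv`,
#' `edit_summary.csv`, one `series_*.csv` per trend table, and a
#' `report_meta.yaml` with the report identity and package version. Output
#' is bit-stable for a fixed report.
#'
#' @param report A `monitoring_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "monitoring_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$metrics, "metrics.csv")
  wr(report$moving_average, "moving_average.csv")
  wr(report$flag_summary, "flag_summary.csv")
  wr(report$edit_summary, "edit_summary.csv")
  for (nm in names(report$series))
    wr(report$series[[nm]], paste0("series_", nm, ".csv"))
  meta <- list(scope = report$scope, scope_id = report$scope_id,
               report_month = format(report$report_month, "%Y-%m"),
               span_months = report$span_months,
               package_version = as.character(utils::packageVersion("regqc")))
  yaml::write_yaml(meta, file.path(dir, "report_meta.yaml"))
  paths <- c(paths, file.path(dir, "report_meta.yaml"))
  invisible(paths)
}

#' Read back an exported metric table
#' @param path Path to a `metrics.csv` written by [export_report()].
#' @return The metric-result tibble.
#' @export
read_metric_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    metric_id = "c", category = "c", scope = "c",
                    scope_id = "c", window_start = readr::col_date(),
                    window_end_month = readr::col_date(),
                    numerator = "d", denominator = "d", value = "d",
                    flag = "c"))
}
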
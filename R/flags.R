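#' Flag a metric value against its catalogue definition
#'
#' Bounds are applied inclusively: a value exactly at a printed bound is
#' acceptable. An `NA` value (empty or unusable denominator) yields
#' `insufficient_data`.
#'
#' @param value Numeric metric value, or `NA`.
#' @param definition One catalogue row (see [metric_catalogue()]).
#' @return One of `"acceptable"`, `"out_of_range"`, `"insufficient_data"`.
#' @export
evaluate_flag <- function(value, definition) {
  stopifnot(is.data.frame(definition), nrow(definition) == 1)
  if (length(value) != 1) abort_regqc("value must be scalar", "regqc_bad_value")
  if (is.na(value)) return("insufficient_data")
  lo <- definition$lower_bound
  hi <- definition$upper_bound
  ok <- switch(definition$bound_semantics,
    at_least = value >= lo,
    exact_minimum = value >= lo,
    at_most = value <= hi,
    within_range = value >= lo && value <= hi,
    abort_regqc(paste("unknown bound semantics:", definition$bound_semantics),
                "regqc_bad_definition")
  )
  if (isTRUE(ok)) "acceptable" else "out_of_range"
}

# Assemble one MetricResult row.
metric_result <- function(metric_id, scope, scope_id, window,
                          numerator, denominator, value, catalogue) {
  def <- catalogue[catalogue$metric_id == metric_id, ]
  if (nrow(def) != 1)
    abort_regqc(paste("metric_id not in catalogue:", metric_id),
                "regqc_unknown_metric")
  tibble::tibble(
    metric_id = metric_id,
    category = def$category,
    scope = scope,
    scope_id = scope_id,
    window_start = window$start,
    window_end_month = window$end,
    numerator = as.numeric(numerator),
    denominator = as.numeric(denominator),
    value = as.numeric(value),
    flag = evaluate_flag(value, def)
  )
}

#' Define an analysis window
#'
#' A window is a span of whole calendar months ending at `as_of_month`,
#' inclusive. Rolling indicators default to 6 months; annual summaries use 12.
#'
#' @param as_of_month Last month of the window (`Date` or `"YYYY-MM"`).
#' @param span_months Number of calendar months covered (default 6).
#' @return A list with `start`, `end` (month-start Dates), `end_day` (last
#'   calendar day of the window) and `months` (vector of month starts).
#' @export
analysis_window <- function(as_of_month, span_months = 6) {
  stopifnot(span_months >= 1)
  end <- as_month(as_of_month)
  start <- month_add(end, -(span_months - 1L))
  list(start = start, end = end,
       end_day = month_add(end, 1L) - 1L,
       months = month_seq(start, end))
}
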
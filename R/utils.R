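#' @importFrom rlang .data %||%
#' @importFrom stats rpois rbinom runif rnorm rlnorm setNames median quantile
#' @importFrom utils head modifyList
NULL

# First day of the calendar month containing x.
month_floor <- function(x) {
  x <- as.Date(x)
  as.Date(format(x, "%Y-%m-01"))
}

# Sequence of month-start dates, inclusive.
month_seq <- function(from, to) {
  seq(month_floor(from), month_floor(to), by = "month")
}

# Shift a month-start date by n calendar months.
month_add <- function(month, n) {
  seq(month_floor(month), by = "month", length.out = abs(n) + 1L)[abs(n) + 1L] ->
    fwd
  if (n >= 0) return(fwd)
  seq(month_floor(month), by = "-1 month", length.out = -n + 1L)[-n + 1L]
}

# Parse "YYYY-MM" or any ISO date into a month-start Date.
as_month <- function(x) {
  if (inherits(x, "Date")) return(month_floor(x))
  x <- as.character(x)
  x <- ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-01"), x)
  month_floor(as.Date(x))
}

days_between <- function(from, to) as.integer(as.Date(to) - as.Date(from))

`%|na|%` <- function(x, y) {
  x[is.na(x)] <- y
  x
}

abort_regqc <- function(msg, class) {
  rlang::abort(msg, class = c(class, "regqc_error"))
}
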
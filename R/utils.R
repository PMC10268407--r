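# Shared numeric / date helpers.

#' Convert a duration in days to months
#'
#' Durations are measured in days and reported in months using the mean
#' Gregorian month of 30.4375 days, so that every reported month value is a
#' deterministic function of the two calendar dates involved.
#'
#' @param days Numeric vector of day counts.
#' @return Numeric vector of month values.
#' @export
#' @examples
#' days_to_months(152) # 4.994...
days_to_months <- function(days) days / 30.4375

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; clinical reporting conventionally
#' rounds half away from zero (62.5% prints as 63%). Used by every reporting
#' surface in the package.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Parse ISO-8601 dates strictly; returns Date with NA for unparseable input.
parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & nzchar(x)
  parsed <- as.Date(x[ok], format = "%Y-%m-%d")
  # reject things as.Date silently mangles (e.g. "2020-1-1" parses; fine)
  out[ok] <- parsed
  out
}

# NULL-coalescing helper.
`%||%` <- function(a, b) if (is.null(a)) b else a

# Scalar min over possibly-NA/empty date candidates.
min_date <- function(...) {
  d <- c(...)
  d <- d[!is.na(d)]
  if (length(d) == 0) return(as.Date(NA))
  min(d)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Zero-row all-character data.frame with the given column names.
empty_chr_df <- function(cols) {
  as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                stringsAsFactors = FALSE)
}

# rbind a list of data.frames, dropping NULLs; NULL when nothing remains.
rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
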
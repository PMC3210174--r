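#' Convert calendar dates to day-of-year
#'
#' Day-of-year (DOY) is 1-based: January 1 is DOY 1. By default the
#' month-day of each date is mapped onto a non-leap calendar (so March 1
#' is always DOY 60), the convention used for all normal-year bloom-date
#' arithmetic in this package. With `leap = TRUE` the DOY is taken within
#' the date's own calendar year, so dates after February 28 of a leap
#' year are one day larger.
#'
#' @param date a `Date` vector.
#' @param leap if `TRUE`, use the date's own calendar year (leap-aware);
#'   if `FALSE` (default), map the month-day onto a non-leap year.
#' @return integer vector of day-of-year values.
#' @examples
#' date_to_doy(as.Date("2001-04-02"))  # 92
#' date_to_doy(as.Date("2000-04-02"))  # still 92
#' date_to_doy(as.Date("2000-04-02"), leap = TRUE)  # 93
#' @seealso [doy_to_date()]
#' @export
date_to_doy <- function(date, leap = FALSE) {
  stopifnot(inherits(date, "Date"))
  if (leap) {
    lt <- as.POSIXlt(date)
    return(as.integer(lt$yday + 1L))
  }
  lt <- as.POSIXlt(date)
  remapped <- as.Date(sprintf("2001-%02d-%02d", lt$mon + 1L, lt$mday))
  if (anyNA(remapped) && !anyNA(date)) {
    stop("cannot map Feb 29 onto a non-leap day-of-year scale", call. = FALSE)
  }
  as.integer(as.POSIXlt(remapped)$yday + 1L)
}

#' Convert day-of-year to a calendar date
#'
#' @param doy integer day-of-year (1-based).
#' @param year calendar year used to anchor the date; defaults to the
#'   non-leap nominal year 2001 used for normal-year arithmetic.
#' @return a `Date` vector.
#' @examples
#' doy_to_date(92)  # "2001-04-02"
#' @export
doy_to_date <- function(doy, year = 2001L) {
  stopifnot(is.numeric(doy), all(is.finite(doy)))
  as.Date(sprintf("%d-01-01", year)) + (doy - 1)
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
}

season_label <- function(start_year) {
  sprintf("%d-%d", start_year, start_year + 1L)
}
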
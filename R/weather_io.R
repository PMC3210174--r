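#' Read a daily station temperature CSV
#'
#' Reads a CSV of daily maximum/minimum air temperatures (degrees C),
#' screens it, and returns a tibble of clean records sorted by date.
#' Header names are configurable so NOAA daily-summary exports (e.g.
#' columns `DATE`, `TMAX`, `TMIN`) can be read without reshaping.
#'
#' Screening rules:
#' * rows with unparseable dates or non-numeric temperatures are dropped
#'   and reported with their file line numbers;
#' * rows with `tmax < tmin` are physically inconsistent and dropped;
#' * temperatures outside the plausibility window \[-60, 60\] degrees C
#'   are flagged but the rows are kept (they may be genuine extremes).
#'
#' All dropped or flagged rows are collected into a rejects report
#' available via [weather_problems()].
#'
#' @param path path to the CSV file.
#' @param col_date,col_tmax,col_tmin header names of the date, maximum
#'   and minimum temperature columns.
#' @return a tibble with columns `date` (`Date`), `tmax`, `tmin`
#'   (numeric, degrees C), sorted by date, carrying the rejects report in
#'   attribute `"problems"`.
#' @seealso [weather_problems()], [extract_season()]
#' @export
read_daily_weather <- function(path, col_date = "date", col_tmax = "tmax",
                               col_tmin = "tmin") {
  if (!file.exists(path)) {
    stop("weather file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(col_date, col_tmax, col_tmin)) {
    if (!col %in% names(raw)) {
      stop("column '", col, "' not found in ", path,
           " (available: ", paste(names(raw), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  n <- nrow(raw)
  problems <- tibble(line = integer(), reason = character())
  if (n == 0L) {
    out <- tibble(date = as.Date(character()), tmax = numeric(),
                  tmin = numeric())
    attr(out, "problems") <- problems
    return(out)
  }
  line_no <- seq_len(n) + 1L  # +1 for the header line
  date <- suppressWarnings(as.Date(as.character(raw[[col_date]])))
  tmax <- suppressWarnings(as.numeric(raw[[col_tmax]]))
  tmin <- suppressWarnings(as.numeric(raw[[col_tmin]]))

  add_problem <- function(idx, reason) {
    if (any(idx)) {
      problems <<- rbind(problems,
                         tibble(line = line_no[idx], reason = reason))
    }
    idx
  }
  bad_date <- add_problem(is.na(date), "unparseable date")
  bad_num  <- add_problem(!bad_date & (is.na(tmax) | is.na(tmin)),
                          "non-numeric temperature")
  usable <- !bad_date & !bad_num
  inverted <- usable & tmax < tmin
  add_problem(inverted, "tmax < tmin")
  # plausibility screen: flagged, not dropped
  extreme <- usable & !inverted &
    (tmax > 60 | tmax < -60 | tmin > 60 | tmin < -60)
  add_problem(extreme, "temperature outside [-60, 60] C")

  keep <- usable & !inverted
  out <- tibble(date = date[keep], tmax = tmax[keep], tmin = tmin[keep])
  out <- out[order(out$date), , drop = FALSE]
  problems <- problems[order(problems$line), , drop = FALSE]
  attr(out, "problems") <- problems
  out
}

#' Rejects report of a weather table
#'
#' @param weather a tibble returned by [read_daily_weather()].
#' @return a tibble with columns `line` (file line number) and `reason`;
#'   zero rows when every row was clean.
#' @export
weather_problems <- function(weather) {
  p <- attr(weather, "problems")
  if (is.null(p)) p <- tibble(line = integer(), reason = character())
  p
}

#' Write daily weather records to CSV
#'
#' Inverse of [read_daily_weather()] with default column names; a
#' read-write-read round trip is the identity on clean records.
#'
#' @param weather tibble with columns `date`, `tmax`, `tmin`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_daily_weather <- function(weather, path) {
  stopifnot(all(c("date", "tmax", "tmin") %in% names(weather)))
  write.csv(weather[, c("date", "tmax", "tmin")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Assemble a dormancy season from daily records
#'
#' A dormancy season runs from October 1 of `start_year` (the assumed
#' onset of endodormancy) through June 30 of the following year: 273
#' days, or 274 when the second calendar year is a leap year. Internal
#' gaps of at most `max_gap` consecutive missing days are filled by
#' linear interpolation of `tmax` and `tmin` independently; longer gaps,
#' or missing boundary dates, reject the season. Chill accumulation is a
#' running sum, so long gaps would bias it.
#'
#' @param weather tibble of daily records (columns `date`, `tmax`,
#'   `tmin`), e.g. from [read_daily_weather()].
#' @param start_year calendar year containing the October 1 onset.
#' @param max_gap maximum run of missing days filled by interpolation.
#' @return a `dormancy_season` object: a list with elements `label`
#'   (e.g. `"2009-2010"`), `start_year`, `onset` (`Date`), and `records`
#'   (complete daily tibble).
#' @examples
#' wx <- simulate_weather(n_years = 1, start_year = 2009, seed = 1)
#' season <- extract_season(wx, 2009)
#' season
#' @export
extract_season <- function(weather, start_year, max_gap = 3L) {
  stopifnot(all(c("date", "tmax", "tmin") %in% names(weather)),
            length(start_year) == 1L, max_gap >= 0)
  start_year <- as.integer(start_year)
  onset <- as.Date(sprintf("%d-10-01", start_year))
  final <- as.Date(sprintf("%d-06-30", start_year + 1L))
  full_dates <- seq(onset, final, by = "day")

  sub <- weather[weather$date >= onset & weather$date <= final, , drop = FALSE]
  if (anyDuplicated(sub$date)) {
    stop("duplicate dates in season ", season_label(start_year), ": ",
         paste(unique(sub$date[duplicated(sub$date)]), collapse = ", "),
         call. = FALSE)
  }
  idx <- match(full_dates, sub$date)
  missing <- is.na(idx)
  if (missing[1L] || missing[length(missing)]) {
    stop("season ", season_label(start_year),
         " rejected: boundary date missing (",
         if (missing[1L]) format(onset) else format(final), ")",
         call. = FALSE)
  }
  if (any(missing)) {
    runs <- rle(missing)
    if (any(runs$lengths[runs$values] > max_gap)) {
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      bad <- which(runs$values & runs$lengths > max_gap)
      gaps <- vapply(bad, function(i) {
        sprintf("%s..%s (%d days)", format(full_dates[starts[i]]),
                format(full_dates[ends[i]]), runs$lengths[i])
      }, character(1))
      stop("season ", season_label(start_year), " rejected: gap(s) longer ",
           "than ", max_gap, " days: ", paste(gaps, collapse = "; "),
           call. = FALSE)
    }
  }
  t_num <- as.numeric(full_dates)
  tmax <- sub$tmax[idx]
  tmin <- sub$tmin[idx]
  if (any(missing)) {
    tmax <- approx(t_num[!missing], tmax[!missing], xout = t_num)$y
    tmin <- approx(t_num[!missing], tmin[!missing], xout = t_num)$y
  }
  structure(
    list(label = season_label(start_year),
         start_year = start_year,
         onset = onset,
         records = tibble(date = full_dates, tmax = tmax, tmin = tmin)),
    class = "dormancy_season")
}

#' @export
print.dormancy_season <- function(x, ...) {
  cat("<dormancy_season> ", x$label, ": ", format(x$onset), " to ",
      format(x$records$date[nrow(x$records)]), " (", nrow(x$records),
      " days)\n", sep = "")
  invisible(x)
}

#' Read observed peak bloom dates
#'
#' Observed PBD records pair a season start year (the year of the
#' October 1 dormancy onset) with the bloom date observed in the
#' following spring. The bloom date must fall between January 1 and
#' June 30 of the season's second calendar year; duplicate seasons are
#' an error.
#'
#' @param path CSV with columns `season_start_year` and `bloom_date`
#'   (ISO-8601), or as renamed via `col_year` / `col_date`.
#' @param col_year,col_date header names.
#' @return tibble with columns `start_year` (integer) and `bloom_date`
#'   (`Date`), one row per season.
#' @export
read_observed_pbd <- function(path, col_year = "season_start_year",
                              col_date = "bloom_date") {
  if (!file.exists(path)) {
    stop("PBD file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(col_year, col_date)) {
    if (!col %in% names(raw)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  year <- suppressWarnings(as.integer(raw[[col_year]]))
  date <- suppressWarnings(as.Date(as.character(raw[[col_date]])))
  if (anyNA(year) || anyNA(date)) {
    stop("unparseable year or bloom date at row(s) ",
         paste(which(is.na(year) | is.na(date)), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(year)) {
    stop("duplicate season(s): ",
         paste(unique(year[duplicated(year)]), collapse = ", "),
         call. = FALSE)
  }
  lo <- as.Date(sprintf("%d-01-01", year + 1L))
  hi <- as.Date(sprintf("%d-06-30", year + 1L))
  bad <- date < lo | date > hi
  if (any(bad)) {
    stop("bloom date outside the Jan 1-Jun 30 window of the season's ",
         "second year: ",
         paste(sprintf("%d -> %s", year[bad], format(date[bad])),
               collapse = ", "),
         call. = FALSE)
  }
  out <- tibble(start_year = year, bloom_date = date)
  out[order(out$start_year), , drop = FALSE]
}
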
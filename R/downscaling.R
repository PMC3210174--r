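mid_month_doys <- c(15L, 46L, 74L, 105L, 135L, 166L, 196L, 227L, 258L,
                    288L, 319L, 349L)

# 365-day harmonic basis evaluated at days d: intercept, five
# sine/cosine harmonic pairs, and the sixth (Nyquist) cosine -- twelve
# functions, so twelve monthly anchors determine the curve exactly.
harmonic_basis <- function(d) {
  theta <- 2 * pi * d / 365
  cols <- list(rep(1, length(d)))
  for (k in 1:5) {
    cols[[length(cols) + 1L]] <- cos(k * theta)
    cols[[length(cols) + 1L]] <- sin(k * theta)
  }
  cols[[length(cols) + 1L]] <- cos(6 * theta)
  do.call(cbind, cols)
}

#' Trigonometric interpolation of monthly values to daily
#'
#' Temporally downscales twelve monthly values (e.g. climatological
#' normals of monthly mean daily maximum temperature) to a 365-day
#' series by exact trigonometric interpolation: a mean term, harmonics
#' 1-5, and the sixth-harmonic cosine term -- twelve coefficients solved
#' exactly so the curve passes through all twelve values, anchored at
#' the mid-month days of year 15, 46, 74, 105, 135, 166, 196, 227, 258,
#' 288, 319, 349. The result is periodic with period 365 (day 365 is
#' adjacent to day 1), as befits a climatological normal year; no leap
#' day exists on this scale.
#'
#' Constant inputs yield a constant series, and any first-harmonic
#' annual cycle sampled at the anchors is reproduced exactly; the
#' operator is linear in its input.
#'
#' @param values numeric vector of 12 finite monthly values
#'   (January..December).
#' @return numeric vector of 365 daily values indexed by day of year.
#' @examples
#' daily <- trig_interpolate_monthly(c(1, 2, 5, 10, 16, 21,
#'                                     24, 23, 19, 13, 7, 3))
#' daily[15]  # equals the January value
#' @export
trig_interpolate_monthly <- function(values) {
  if (length(values) != 12L || !all(is.finite(values))) {
    stop("values must be 12 finite monthly numbers", call. = FALSE)
  }
  coef <- solve(harmonic_basis(mid_month_doys), values)
  as.numeric(harmonic_basis(1:365) %*% coef)
}

#' Monthly temperature normals for one location and period
#'
#' @param location_id location identifier.
#' @param period normal-period label (e.g. `"2020s"` for 2010-2039).
#' @param tmax,tmin numeric vectors of 12 monthly normals, degrees C,
#'   with `tmax[m] >= tmin[m]` for every month.
#' @param scenario optional emissions-scenario label (e.g. `"A1B"`).
#' @return a `monthly_normals` object.
#' @export
monthly_normals <- function(location_id, period, tmax, tmin,
                            scenario = NA_character_) {
  stopifnot(length(tmax) == 12L, length(tmin) == 12L,
            all(is.finite(tmax)), all(is.finite(tmin)))
  if (any(tmax < tmin)) {
    stop("tmax < tmin in month(s) ",
         paste(which(tmax < tmin), collapse = ", "), call. = FALSE)
  }
  structure(list(location_id = as.character(location_id),
                 period = as.character(period),
                 scenario = as.character(scenario),
                 tmax = as.numeric(tmax), tmin = as.numeric(tmin)),
            class = "monthly_normals")
}

#' @export
print.monthly_normals <- function(x, ...) {
  cat("<monthly_normals> ", x$location_id,
      if (!is.na(x$scenario) && nzchar(x$scenario))
        paste0(" [", x$scenario, "]"), " ",
      x$period, "\n", sep = "")
  cat("  tmax:", paste(sprintf("%.1f", x$tmax), collapse = " "), "\n")
  cat("  tmin:", paste(sprintf("%.1f", x$tmin), collapse = " "), "\n")
  invisible(x)
}

#' Downscale monthly normals to a daily climatology
#'
#' Interpolates the twelve monthly `tmax` and `tmin` normals
#' independently with [trig_interpolate_monthly()]. Because the two
#' curves are fitted independently they can cross on days when the
#' monthly diurnal range pinches to zero; such days are clamped -- both
#' series set to their midpoint -- and counted in the `n_clamped`
#' diagnostic.
#'
#' @param normals a [monthly_normals()] object.
#' @return a `daily_climatology` object: list with `location_id`,
#'   `period`, `scenario`, `daily` (tibble of `doy`, `tmax`, `tmin`,
#'   365 rows), and `n_clamped`.
#' @export
downscale_normals <- function(normals) {
  stopifnot(inherits(normals, "monthly_normals"))
  tmax <- trig_interpolate_monthly(normals$tmax)
  tmin <- trig_interpolate_monthly(normals$tmin)
  crossed <- tmax < tmin
  if (any(crossed)) {
    mid <- (tmax[crossed] + tmin[crossed]) / 2
    tmax[crossed] <- mid
    tmin[crossed] <- mid
  }
  structure(
    list(location_id = normals$location_id, period = normals$period,
         scenario = normals$scenario,
         daily = tibble(doy = 1:365, tmax = tmax, tmin = tmin),
         n_clamped = sum(crossed)),
    class = "daily_climatology")
}

#' @export
print.daily_climatology <- function(x, ...) {
  cat("<daily_climatology> ", x$location_id,
      if (!is.na(x$scenario) && nzchar(x$scenario))
        paste0(" [", x$scenario, "]"), " ",
      x$period, ": 365 days", sep = "")
  if (x$n_clamped > 0) cat(" (", x$n_clamped, " crossing days clamped)",
                           sep = "")
  cat("\n")
  invisible(x)
}

#' Wrap a daily climatology into a normal-year dormancy season
#'
#' Builds the October 1 - June 30 dormancy season of a repeating
#' 365-day normal year: days of year 274-365 followed by 1-181 (273
#' days), labelled with nominal non-leap calendar years so the chill
#' model can consume it like any observed season.
#'
#' @param clim a `daily_climatology` from [downscale_normals()].
#' @param start_year nominal start year of the season labels; its
#'   successor must not be a leap year (default 2001).
#' @return a `dormancy_season` object.
#' @export
climatology_to_season <- function(clim, start_year = 2001L) {
  stopifnot(inherits(clim, "daily_climatology"))
  start_year <- as.integer(start_year)
  if (is_leap_year(start_year + 1L)) {
    stop("start_year + 1 must not be a leap year on the 365-day normal ",
         "scale (got ", start_year + 1L, ")", call. = FALSE)
  }
  doys <- c(274:365, 1:181)
  onset <- as.Date(sprintf("%d-10-01", start_year))
  dates <- seq(onset, by = "day", length.out = length(doys))
  structure(
    list(label = season_label(start_year), start_year = start_year,
         onset = onset,
         records = tibble(date = dates,
                          tmax = clim$daily$tmax[doys],
                          tmin = clim$daily$tmin[doys])),
    class = "dormancy_season")
}

#' Read monthly climate normals from CSV
#'
#' Expects the long layout a CCAFS-style extract can be reshaped into:
#' columns `location_id`, `period`, `month` (1-12), `tmax`, `tmin`, and
#' optionally `scenario`. Every (location, scenario, period) group must
#' have exactly 12 months.
#'
#' @param path CSV path.
#' @return tibble with one row per location/scenario/period/month.
#' @seealso [split_normals()] to turn the table into
#'   [monthly_normals()] objects.
#' @export
read_monthly_normals <- function(path) {
  if (!file.exists(path)) {
    stop("normals file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("location_id", "period", "month", "tmax", "tmin")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("normals CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"scenario" %in% names(raw)) raw$scenario <- NA_character_
  out <- as_tibble(raw[, c("location_id", "scenario", "period", "month",
                           "tmax", "tmin")])
  key <- normals_key(out)
  counts <- table(key)
  if (any(counts != 12L)) {
    stop("each location/scenario/period needs exactly 12 monthly rows; ",
         "offending group(s): ",
         paste(names(counts)[counts != 12L], collapse = ", "),
         call. = FALSE)
  }
  out[order(out$location_id, out$scenario, out$period, out$month), ,
      drop = FALSE]
}

normals_key <- function(tbl) {
  scen <- tbl$scenario
  scen[is.na(scen)] <- ""
  factor(paste(tbl$location_id, scen, tbl$period, sep = "|"))
}

#' Split a normals table into monthly_normals objects
#'
#' @param normals_tbl tibble as returned by [read_monthly_normals()].
#' @return a list of [monthly_normals()] objects, one per
#'   location/scenario/period group.
#' @export
split_normals <- function(normals_tbl) {
  key <- normals_key(normals_tbl)
  lapply(split(normals_tbl, key), function(g) {
    g <- g[order(g$month), , drop = FALSE]
    monthly_normals(g$location_id[1], g$period[1], g$tmax, g$tmin,
                    scenario = g$scenario[1])
  })
}
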
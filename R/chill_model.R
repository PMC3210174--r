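#' Cultivar parameters of the chill-day model
#'
#' The two-stage model is governed by three cultivar-specific
#' parameters: `tc`, the base threshold temperature (degrees C)
#' separating chilling from forcing contributions; `rc`, the chilling
#' requirement in chill days (a negative number, since chill days
#' accumulate as negative units); and `rh`, the heating requirement in
#' anti-chill days (positive). Endodormancy is released when the
#' accumulated chill days reach `rc`; peak bloom occurs when the
#' anti-chill days accumulated after release reach `rh`.
#'
#' Published estimates for the Tidal Basin cherries are
#' `chill_params(4.3, -78.9, 221.2)` for Yoshino
#' (*Prunus x yedoensis*) and `chill_params(5.3, -114.0, 289.1)` for
#' Kwanzan (*Prunus serrulata*).
#'
#' @param tc threshold temperature, degrees C; must be finite and
#'   non-negative (the daily contribution formulas assume the threshold
#'   sits at or above the 0 C lower bound).
#' @param rc chilling requirement, chill days; strictly negative.
#' @param rh heating requirement, anti-chill days; strictly positive.
#' @return a `chill_params` object.
#' @export
chill_params <- function(tc, rc, rh) {
  stopifnot(length(tc) == 1L, length(rc) == 1L, length(rh) == 1L)
  if (!is.finite(tc) || tc < 0) {
    stop("tc must be finite and >= 0 (got ", tc, ")", call. = FALSE)
  }
  if (!is.finite(rc) || rc >= 0) {
    stop("rc must be a negative number of chill days (got ", rc, ")",
         call. = FALSE)
  }
  if (!is.finite(rh) || rh <= 0) {
    stop("rh must be a positive number of anti-chill days (got ", rh, ")",
         call. = FALSE)
  }
  structure(list(tc = as.numeric(tc), rc = as.numeric(rc),
                 rh = as.numeric(rh)),
            class = "chill_params")
}

#' @export
print.chill_params <- function(x, ...) {
  cat(sprintf(
    "<chill_params> Tc = %g C, Rc = %g chill days, Rh = %g anti-chill days\n",
    x$tc, x$rc, x$rh))
  invisible(x)
}

# Numeric core of the daily contributions; vectorised, no validation.
# Single-triangle rules with a 0 C lower bound: the diurnal course is a
# triangle wave between tmin and tmax, chilling is (minus) the mean area
# between min(T, tc) and max(tmin, 0), forcing the mean area above tc.
chill_cd_ca <- function(tmax, tmin, tc) {
  n <- length(tmax)
  tc <- rep_len(tc, n)
  ta <- (tmax + tmin) / 2
  cd <- numeric(n)
  ca <- numeric(n)
  case <- character(n)

  sub0 <- tmax < 0
  iso <- !sub0 & tmax == tmin
  tri <- !sub0 & !iso
  span2 <- 2 * (tmax - tmin)  # guarded: only used where tmax > tmin

  case[sub0] <- "subzero"                        # whole day below 0 C
  if (any(iso)) {
    case[iso] <- "isothermal"                    # collapsed triangle
    ca[iso] <- pmax(0, ta[iso] - tc[iso])
  }

  c1 <- tri & tmin >= 0 & tmin >= tc
  c2 <- tri & tmin >= 0 & tmin < tc & tmax > tc
  c3 <- tri & tmin >= 0 & tmax <= tc & tmin < tc
  c4 <- tri & tmin < 0 & tmax <= tc
  c5 <- tri & tmin < 0 & tmax > tc

  case[c1] <- "1"; case[c2] <- "2"; case[c3] <- "3"
  case[c4] <- "4"; case[c5] <- "5"

  ca[c1] <- ta[c1] - tc[c1]
  ca[c2] <- (tmax[c2] - tc[c2])^2 / span2[c2]
  cd[c2] <- -((ta[c2] - tmin[c2]) - ca[c2])
  cd[c3] <- -(ta[c3] - tmin[c3])
  cd[c4] <- -tmax[c4]^2 / span2[c4]
  ca[c5] <- (tmax[c5] - tc[c5])^2 / span2[c5]
  cd[c5] <- -(tmax[c5]^2 / span2[c5] - ca[c5])

  list(cd = cd, ca = ca, case = case)
}

#' Daily chill-day and anti-chill-day contributions
#'
#' Computes one day's chilling (`cd`, chill days, always <= 0) and
#' forcing (`ca`, anti-chill days, always >= 0) contributions from the
#' daily maximum and minimum temperature and the threshold `tc`,
#' following the single-triangle rules with the daily mean
#' `Ta = (tmax + tmin) / 2` and a 0 C lower bound. With `Tn = tmin`,
#' `Tx = tmax`:
#'
#' * case 1 (`0 <= tc <= Tn <= Tx`): `cd = 0`, `ca = Ta - tc`
#' * case 2 (`0 <= Tn <= tc < Tx`): `ca = (Tx - tc)^2 / (2 (Tx - Tn))`,
#'   `cd = -((Ta - Tn) - ca)`
#' * case 3 (`0 <= Tn <= Tx <= tc`): `cd = -(Ta - Tn)`, `ca = 0`
#' * case 4 (`Tn < 0 <= Tx <= tc`): `cd = -Tx^2 / (2 (Tx - Tn))`, `ca = 0`
#' * case 5 (`Tn < 0 <= tc < Tx`): `ca = (Tx - tc)^2 / (2 (Tx - Tn))`,
#'   `cd = -(Tx^2 / (2 (Tx - Tn)) - ca)`
#'
#' Isothermal days (`Tx == Tn`) take the collapsed-triangle limit
#' `cd = 0`, `ca = max(0, Ta - tc)`; days entirely below freezing
#' (`Tx < 0`) contribute nothing.
#'
#' @param tmax,tmin daily maximum and minimum temperature, degrees C;
#'   vectors of equal length with `tmax >= tmin`.
#' @param tc threshold temperature, degrees C, >= 0; a scalar or a
#'   vector parallel to `tmax`.
#' @return tibble with columns `cd`, `ca`, and `case` (`"1"`..`"5"`,
#'   `"isothermal"`, or `"subzero"`).
#' @examples
#' chill_day(tmax = 14, tmin = 6, tc = 4.3)  # case 1: ca = 5.7
#' chill_day(tmax = 4, tmin = 0, tc = 5.3)   # case 3: cd = -2
#' @export
chill_day <- function(tmax, tmin, tc) {
  stopifnot(length(tmax) == length(tmin),
            length(tc) == 1L || length(tc) == length(tmax),
            all(is.finite(tc)), all(tc >= 0))
  if (any(tmax < tmin)) {
    stop("tmax < tmin at position(s) ",
         paste(which(tmax < tmin), collapse = ", "), call. = FALSE)
  }
  res <- chill_cd_ca(tmax, tmin, tc)
  tibble(cd = res$cd, ca = res$ca, case = res$case)
}

#' Run the two-stage model over one dormancy season
#'
#' Chill days accumulate (as a non-increasing running sum `dc`) from the
#' October 1 onset. The first day whose end-of-day `dc` reaches the
#' chilling requirement (`dc <= rc`) releases endodormancy; anti-chill
#' days then accumulate from the *following* day (forcing accrued before
#' release is discarded) into a non-decreasing sum `dh`. Peak bloom is
#' the first day with `dh >= rh`. Threshold crossings are whole-day: no
#' sub-day interpolation is attempted. Chill accumulation is frozen at
#' its release value once forcing begins.
#'
#' @param season a `dormancy_season` from [extract_season()] or
#'   [climatology_to_season()].
#' @param params a [chill_params()] object.
#' @return a `bloom_prediction` object: list with `label`, `start_year`,
#'   `release_date` (`Date` or `NA`), `bloom_date` (`Date` or `NA`),
#'   `status` (`"bloomed"`, `"no-release"`, or `"no-bloom"`), `params`,
#'   and `trajectory`, a daily tibble of `date`, `cd`, `ca`, `dc`, `dh`.
#' @examples
#' wx <- simulate_weather(n_years = 1, start_year = 2005, seed = 42)
#' run_season(extract_season(wx, 2005), chill_params(4.3, -78.9, 221.2))
#' @export
run_season <- function(season, params) {
  if (!inherits(season, "dormancy_season")) {
    stop("season must be a dormancy_season object", call. = FALSE)
  }
  if (!inherits(params, "chill_params")) {
    stop("params must be a chill_params object", call. = FALSE)
  }
  rec <- season$records
  if (anyNA(rec$tmax) || anyNA(rec$tmin)) {
    stop("season ", season$label, " has missing temperatures", call. = FALSE)
  }
  n <- nrow(rec)
  contrib <- chill_cd_ca(rec$tmax, rec$tmin, params$tc)
  dc_raw <- cumsum(contrib$cd)
  ca_cum <- cumsum(contrib$ca)

  ri <- first_at_or_below(dc_raw, params$rc)
  dc <- dc_raw
  dh <- numeric(n)
  release_date <- as.Date(NA)
  bloom_date <- as.Date(NA)
  status <- "no-release"
  if (ri <= n) {
    release_date <- rec$date[ri]
    dc[ri:n] <- dc_raw[ri]            # chilling frozen once released
    dh <- pmax(0, ca_cum - ca_cum[ri])
    dh[seq_len(ri)] <- 0
    bi <- first_at_or_above(ca_cum, params$rh + ca_cum[ri])
    if (bi <= n) {
      status <- "bloomed"
      bloom_date <- rec$date[bi]
    } else {
      status <- "no-bloom"
    }
  }
  structure(
    list(label = season$label, start_year = season$start_year,
         release_date = release_date, bloom_date = bloom_date,
         status = status, params = params,
         trajectory = tibble(date = rec$date, cd = contrib$cd,
                             ca = contrib$ca, dc = dc, dh = dh)),
    class = "bloom_prediction")
}

#' @export
print.bloom_prediction <- function(x, ...) {
  cat("<bloom_prediction> season ", x$label, ": ", x$status, sep = "")
  if (!is.na(x$release_date)) {
    cat(", dormancy released ", format(x$release_date), sep = "")
  }
  if (!is.na(x$bloom_date)) {
    cat(", peak bloom ", format(x$bloom_date), sep = "")
  }
  cat("\n")
  invisible(x)
}

# first index with non-increasing x[i] <= target, length(x) + 1 if none
first_at_or_below <- function(x, target) {
  first_at_or_above(-x, -target)
}

# first index with non-decreasing x[i] >= target, length(x) + 1 if none
first_at_or_above <- function(x, target) {
  findInterval(target, x, left.open = TRUE) + 1L
}

#' Predict peak bloom dates for many seasons
#'
#' Extracts each requested dormancy season from a multi-year daily
#' weather table and runs the two-stage model on it. Seasons whose
#' weather fails quality control (gaps longer than `max_gap`, missing
#' boundaries) are reported in the result, not silently skipped.
#'
#' @param weather daily weather tibble (columns `date`, `tmax`, `tmin`).
#' @param params a [chill_params()] object.
#' @param start_years integer vector of season start years; by default
#'   every season fully covered by `weather`.
#' @param max_gap forwarded to [extract_season()].
#' @return tibble with one row per requested season: `start_year`,
#'   `season`, `release_date`, `bloom_date`, `bloom_doy` (leap-aware DOY
#'   of the bloom date), and `status` (`"bloomed"`, `"no-release"`,
#'   `"no-bloom"`, or `"weather-rejected"`). QC failure messages are in
#'   attribute `"failures"`.
#' @export
predict_pbd <- function(weather, params, start_years = NULL, max_gap = 3L) {
  if (is.null(start_years)) {
    start_years <- covered_start_years(weather)
    if (length(start_years) == 0L) {
      stop("weather does not fully cover any Oct 1-Jun 30 season",
           call. = FALSE)
    }
  }
  start_years <- sort(as.integer(start_years))
  rows <- vector("list", length(start_years))
  failures <- tibble(start_year = integer(), reason = character())
  for (i in seq_along(start_years)) {
    sy <- start_years[i]
    pred <- tryCatch(
      run_season(extract_season(weather, sy, max_gap = max_gap), params),
      error = function(e) conditionMessage(e))
    if (is.character(pred)) {
      failures <- rbind(failures, tibble(start_year = sy, reason = pred))
      rows[[i]] <- tibble(start_year = sy, season = season_label(sy),
                          release_date = as.Date(NA),
                          bloom_date = as.Date(NA),
                          bloom_doy = NA_integer_,
                          status = "weather-rejected")
    } else {
      rows[[i]] <- tibble(
        start_year = sy, season = pred$label,
        release_date = pred$release_date, bloom_date = pred$bloom_date,
        bloom_doy = if (is.na(pred$bloom_date)) NA_integer_ else
          date_to_doy(pred$bloom_date, leap = TRUE),
        status = pred$status)
    }
  }
  if (nrow(failures) == length(start_years)) {
    stop("no requested season has usable weather; first problem: ",
         failures$reason[1L], call. = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

# start years whose full Oct 1-Jun 30 span lies inside the date range
covered_start_years <- function(weather) {
  if (nrow(weather) == 0L) return(integer())
  rng <- range(weather$date)
  years <- seq(as.POSIXlt(rng[1])$year + 1899L,
               as.POSIXlt(rng[2])$year + 1901L)
  years[as.Date(sprintf("%d-10-01", years)) >= rng[1] &
          as.Date(sprintf("%d-06-30", years + 1L)) <= rng[2]]
}
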
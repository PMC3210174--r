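#' Simulate mid-latitude daily station weather
#'
#' Generates a multi-year daily temperature series with the statistical
#' structure of a mid-latitude station record: a sinusoidal annual
#' cycle in the daily mean, AR(1)-autocorrelated Gaussian weather noise
#' (so chill sums see realistic day-to-day persistence), and a jittered
#' diurnal range splitting the mean into `tmax`/`tmin`. The daily mean
#' on day `d` (counted from January 1 of `start_year`) is
#' `annual_mean - annual_amplitude * cos(2 * pi * (d - phase_doy) / 365.25)`
#' plus stationary AR(1) noise with marginal standard deviation
#' `noise_sd` and lag-1 autocorrelation `ar1`. The 365.25-day sinusoid
#' keeps multi-year series aligned with the calendar without
#' special-casing leap years.
#'
#' The series runs from October 1 of `start_year` through June 30 of
#' `start_year + n_years`, covering `n_years` complete dormancy
#' seasons. Defaults emulate a humid mid-latitude East-Coast climate
#' (annual mean 12 C, amplitude 12 C so January means sit near 0 C and
#' July near 24 C, coldest day around January 15, mean diurnal range
#' 9 C).
#'
#' @param n_years number of complete dormancy seasons to cover.
#' @param start_year calendar year of the first October 1 onset.
#' @param annual_mean annual mean temperature, degrees C.
#' @param annual_amplitude half peak-to-trough seasonal swing, >= 0.
#' @param phase_doy day of year of the seasonal minimum.
#' @param diurnal_range mean daily `tmax - tmin`, > 0 degrees C.
#' @param range_jitter_sd SD of the daily jitter on the diurnal range
#'   (floored at 0.5 C).
#' @param ar1 lag-1 autocorrelation of the weather noise, in \[0, 1).
#' @param noise_sd marginal SD of the weather noise, >= 0.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed (the caller's RNG state is untouched).
#' @return tibble with columns `date`, `tmax`, `tmin`.
#' @export
simulate_weather <- function(n_years, start_year = 2000L, annual_mean = 12,
                             annual_amplitude = 12, phase_doy = 15,
                             diurnal_range = 9, range_jitter_sd = 1,
                             ar1 = 0.7, noise_sd = 1.5, seed = 1L) {
  stopifnot(n_years >= 1, annual_amplitude >= 0, diurnal_range > 0,
            range_jitter_sd >= 0, ar1 >= 0, ar1 < 1, noise_sd >= 0)
  start_year <- as.integer(start_year)
  dates <- seq(as.Date(sprintf("%d-10-01", start_year)),
               as.Date(sprintf("%d-06-30", start_year + n_years)),
               by = "day")
  d <- as.numeric(dates - as.Date(sprintf("%d-01-01", start_year))) + 1
  ta_clim <- annual_mean -
    annual_amplitude * cos(2 * pi * (d - phase_doy) / 365.25)
  n <- length(dates)
  withr::with_seed(seed, {
    noise <- numeric(n)
    if (noise_sd > 0) {
      innov_sd <- noise_sd * sqrt(1 - ar1^2)
      noise[1] <- rnorm(1, 0, noise_sd)
      eps <- rnorm(n - 1, 0, innov_sd)
      for (i in 2:n) noise[i] <- ar1 * noise[i - 1] + eps[i - 1]
    }
    rng <- pmax(0.5, diurnal_range + rnorm(n, 0, range_jitter_sd))
    ta <- ta_clim + noise
    tibble(date = dates, tmax = ta + rng / 2, tmin = ta - rng / 2)
  })
}

#' Simulate observed peak bloom dates from the forward model
#'
#' Runs the two-stage chill model with known "true" parameters over
#' every complete dormancy season in `weather` and adds rounded
#' Gaussian observation noise to the predicted bloom day-of-year,
#' producing an observed-PBD table for parameter-recovery experiments.
#' It is an error for the true parameters to fail to bloom in any
#' season: recovery experiments require a defined truth everywhere.
#'
#' @param weather daily weather tibble covering at least one complete
#'   season (e.g. from [simulate_weather()]).
#' @param params the true [chill_params()].
#' @param noise_sd SD (days) of the Gaussian observation noise; 0 gives
#'   exact forward-model observations.
#' @param seed integer seed (pure-function semantics as in
#'   [simulate_weather()]).
#' @param max_gap forwarded to [extract_season()].
#' @return tibble with columns `start_year`, `bloom_date`, compatible
#'   with [calibrate()] and [read_observed_pbd()] output.
#' @export
simulate_pbd <- function(weather, params, noise_sd = 0, seed = 1L,
                         max_gap = 3L) {
  stopifnot(inherits(params, "chill_params"), noise_sd >= 0)
  preds <- predict_pbd(weather, params, max_gap = max_gap)
  bad <- preds$status != "bloomed"
  if (any(bad)) {
    stop("true parameters fail to bloom in season(s): ",
         paste(preds$season[bad], collapse = ", "), call. = FALSE)
  }
  n <- nrow(preds)
  doy <- withr::with_seed(seed, {
    preds$bloom_doy + round(rnorm(n, 0, noise_sd))
  })
  year <- as.integer(format(preds$bloom_date, "%Y"))
  tibble(start_year = preds$start_year,
         bloom_date = doy_to_date(doy, year))
}
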
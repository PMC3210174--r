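# Numerical-integration oracle for the daily chill/anti-chill
# contributions: the diurnal course is a triangle wave between tmin and
# tmax (linear rise then symmetric fall, so averaging over one ramp
# equals averaging over the day). Forcing is the time-mean excess over
# tc; chilling is minus the time-mean of the band between max(tmin, 0)
# and min(T, tc). Midpoint rule; the integrand is piecewise linear so
# m = 4001 cells give ~1e-6 accuracy.
tri_oracle <- function(tmax, tmin, tc, m = 4001L) {
  if (tmax < 0) return(c(cd = 0, ca = 0))
  if (tmax == tmin) {
    return(c(cd = 0, ca = max(0, tmax - tc)))
  }
  u <- (seq_len(m) - 0.5) / m
  temp <- tmin + (tmax - tmin) * u
  c(cd = -mean(pmax(pmin(temp, tc) - max(tmin, 0), 0)),
    ca = mean(pmax(temp - tc, 0)))
}

# Full-season weather table of constant days, or a cold phase followed
# by a warm phase (the hand-accumulation fixture).
season_dates <- function(start_year) {
  seq(as.Date(sprintf("%d-10-01", start_year)),
      as.Date(sprintf("%d-06-30", start_year + 1)), by = "day")
}

constant_weather <- function(start_year, tmax, tmin) {
  dates <- season_dates(start_year)
  tibble::tibble(date = dates, tmax = tmax, tmin = tmin)
}

step_weather <- function(start_year, n_cold = 30, cold = c(4, 2),
                         warm = c(14, 6)) {
  dates <- season_dates(start_year)
  n <- length(dates)
  tibble::tibble(
    date = dates,
    tmax = c(rep(cold[1], n_cold), rep(warm[1], n - n_cold)),
    tmin = c(rep(cold[2], n_cold), rep(warm[2], n - n_cold)))
}

# Washington-DC-like monthly temperature normals (degrees C)
dc_like_normals_tbl <- function(location_id = "DC-like",
                                period = "baseline",
                                scenario = NA_character_,
                                spring_delta = 0) {
  tmax <- c(6, 8, 13, 19, 24, 29, 31, 30, 26, 20, 14, 8)
  tmin <- c(-2, -1, 3, 8, 14, 19, 22, 21, 17, 10, 5, 0)
  delta <- c(0, rep(spring_delta, 5), rep(0, 6))  # Feb-Jun warmed
  tibble::tibble(location_id = location_id, scenario = scenario,
                 period = period, month = 1:12,
                 tmax = tmax + delta, tmin = tmin + delta)
}

yoshino_params <- function() chill_params(4.3, -78.9, 221.2)
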
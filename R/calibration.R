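#' Parameter-search grid
#'
#' Each axis is given as `c(min, max, step)`. The default grid brackets
#' published cherry estimates (threshold 4.3-7.0 C, chilling requirement
#' -78.9 to -114.0 chill days, heating requirement 123.5-289.1
#' anti-chill days) with a wide margin; the local refinement in
#' [calibrate()] then recovers sub-step precision.
#'
#' @param tc threshold-temperature axis, degrees C (`c(min, max, step)`).
#' @param rc chilling-requirement axis; must be entirely negative.
#' @param rh heating-requirement axis; must be entirely positive.
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(tc = c(0, 12, 0.1), rc = c(-200, -20, 1),
                      rh = c(50, 400, 1)) {
  axis <- function(x, name) {
    if (length(x) != 3L || !all(is.finite(x)) || x[3] <= 0 || x[2] < x[1]) {
      stop(name, " axis must be c(min, max, step) with step > 0 and ",
           "max >= min", call. = FALSE)
    }
    x
  }
  tc <- axis(tc, "tc"); rc <- axis(rc, "rc"); rh <- axis(rh, "rh")
  if (tc[1] < 0) stop("tc range must be non-negative", call. = FALSE)
  if (rc[2] >= 0) stop("rc range must be entirely negative", call. = FALSE)
  if (rh[1] <= 0) stop("rh range must be entirely positive", call. = FALSE)
  structure(list(tc = tc, rc = rc, rh = rh), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  fmt <- function(a) sprintf("[%g, %g] step %g", a[1], a[2], a[3])
  cat("<grid_spec> Tc ", fmt(x$tc), "; Rc ", fmt(x$rc), "; Rh ",
      fmt(x$rh), "\n", sep = "")
  invisible(x)
}

grid_axis_values <- function(a) seq(a[1], a[2], by = a[3])

# Seasons usable for fitting: those observations whose dormancy season
# can be assembled from the weather table. Returns a list with the
# season records, observed day-in-season indices, and drop diagnostics.
assemble_fit_seasons <- function(observations, weather, max_gap = 3L) {
  stopifnot(all(c("start_year", "bloom_date") %in% names(observations)))
  observations <- observations[order(observations$start_year), , drop = FALSE]
  seasons <- list()
  obs_idx <- numeric()
  used <- integer()
  dropped <- tibble(start_year = integer(), reason = character())
  for (k in seq_len(nrow(observations))) {
    sy <- observations$start_year[k]
    season <- tryCatch(extract_season(weather, sy, max_gap = max_gap),
                       error = function(e) conditionMessage(e))
    if (is.character(season)) {
      dropped <- rbind(dropped, tibble(start_year = sy, reason = season))
      next
    }
    seasons[[length(seasons) + 1L]] <- season
    obs_idx <- c(obs_idx,
                 as.numeric(observations$bloom_date[k] - season$onset) + 1)
    used <- c(used, sy)
  }
  list(seasons = seasons, obs_idx = obs_idx, used = used, dropped = dropped)
}

# Day-in-season bloom index for one season under (tc, rc, rh); the
# penalty substitutes for the error of no-release / no-bloom seasons.
season_bloom_index <- function(records, tc, rc, rh) {
  contrib <- chill_cd_ca(records$tmax, records$tmin, tc)
  n <- nrow(records)
  dc <- cumsum(contrib$cd)
  ri <- first_at_or_below(dc, rc)
  if (ri > n) return(NA_real_)
  ca_cum <- cumsum(contrib$ca)
  bi <- first_at_or_above(ca_cum, rh + ca_cum[ri])
  if (bi > n) return(NA_real_)
  bi
}

#' Penalised RMSE objective for a parameter set
#'
#' Root-mean-square error (days) between model-predicted and observed
#' peak bloom dates across seasons. A season in which the parameter set
#' never releases dormancy or never reaches the heating requirement
#' contributes `penalty` days as its absolute error rather than being
#' discarded; discarding would reward parameter sets that fail to bloom.
#'
#' @param params a [chill_params()] object.
#' @param observations tibble of observed PBD (`start_year`,
#'   `bloom_date`), e.g. from [read_observed_pbd()].
#' @param weather daily weather tibble covering the observed seasons.
#' @param penalty days of error charged to a non-blooming season.
#' @param max_gap forwarded to [extract_season()].
#' @return the penalised RMSE in days (a single number).
#' @export
penalized_rmse <- function(params, observations, weather, penalty = 60,
                           max_gap = 3L) {
  stopifnot(inherits(params, "chill_params"))
  fit <- assemble_fit_seasons(observations, weather, max_gap = max_gap)
  if (length(fit$seasons) == 0L) {
    stop("no observed season has usable weather", call. = FALSE)
  }
  err <- vapply(seq_along(fit$seasons), function(s) {
    bi <- season_bloom_index(fit$seasons[[s]]$records, params$tc,
                             params$rc, params$rh)
    if (is.na(bi)) penalty else bi - fit$obs_idx[s]
  }, numeric(1))
  sqrt(mean(err^2))
}

# Lexicographic comparator implementing the documented tie-breaks:
# objective, then |bias|, then smallest tc, then rc closest to zero,
# then smallest rh. `a`, `b` are lists with obj, abias, tc, rc, rh.
candidate_better <- function(a, b, tol = 1e-9) {
  keys_a <- c(a$obj, a$abias, a$tc, -a$rc, a$rh)
  keys_b <- c(b$obj, b$abias, b$tc, -b$rc, b$rh)
  for (i in seq_along(keys_a)) {
    if (keys_a[i] < keys_b[i] - tol) return(TRUE)
    if (keys_a[i] > keys_b[i] + tol) return(FALSE)
  }
  FALSE
}

# Exhaustive vectorised sweep of the (rc, rh) plane for each tc value.
# For fixed tc the cumulative chill and forcing sums of a season are
# fixed, so release and bloom indices for a whole (rc, rh) grid reduce
# to two monotone searches (findInterval) per season.
grid_search_engine <- function(seasons, obs_idx, tc_vals, rc_vals, rh_vals,
                               penalty, trace = FALSE) {
  n_seasons <- length(seasons)
  n_rc <- length(rc_vals)
  n_rh <- length(rh_vals)
  rc_grid <- rep(rc_vals, times = n_rh)
  rh_grid <- rep(rh_vals, each = n_rc)
  best <- NULL
  any_bloom <- FALSE
  trace_rows <- if (trace) vector("list", length(tc_vals)) else NULL

  for (ti in seq_along(tc_vals)) {
    tc <- tc_vals[ti]
    sse <- numeric(n_rc * n_rh)
    esum <- numeric(n_rc * n_rh)
    nbloom <- integer(n_rc * n_rh)
    for (s in seq_len(n_seasons)) {
      rec <- seasons[[s]]$records
      contrib <- chill_cd_ca(rec$tmax, rec$tmin, tc)
      n <- nrow(rec)
      dc <- cumsum(contrib$cd)
      ca_cum <- cumsum(contrib$ca)
      ri <- first_at_or_below(dc, rc_vals)            # per rc value
      released <- ri <= n
      # forcing target per (rc, rh) cell; unreleased cells get +Inf
      base <- rep(NA_real_, n_rc)
      base[released] <- ca_cum[ri[released]]
      target <- rep(base, times = n_rh) + rh_grid
      target[is.na(target)] <- Inf
      bi <- first_at_or_above(ca_cum, target)
      ok <- bi <= n
      err <- ifelse(ok, bi - obs_idx[s], penalty)
      sse <- sse + err^2
      esum <- esum + ifelse(ok, err, 0)
      nbloom <- nbloom + ok
    }
    obj <- sqrt(sse / n_seasons)
    abias <- ifelse(nbloom > 0, abs(esum / nbloom), Inf)
    any_bloom <- any_bloom || any(nbloom > 0)
    # best cell for this tc, applying the in-plane tie-breaks
    ord <- order(obj, abias, -rc_grid, rh_grid)
    j <- ord[1L]
    cand <- list(obj = obj[j], abias = abias[j], tc = tc, rc = rc_grid[j],
                 rh = rh_grid[j])
    if (is.null(best) || candidate_better(cand, best)) best <- cand
    if (trace) {
      trace_rows[[ti]] <- tibble(tc = tc, rc = rc_grid[j], rh = rh_grid[j],
                                 objective = obj[j])
    }
  }
  if (!any_bloom) {
    stop("grid infeasible: every parameter combination fails to bloom in ",
         "every season", call. = FALSE)
  }
  best$trace <- if (trace) do.call(rbind, trace_rows) else NULL
  best
}

# Single-point evaluation of the penalised objective plus the tie-break
# bias, on pre-assembled seasons (fast path for refinement).
point_objective <- function(seasons, obs_idx, tc, rc, rh, penalty) {
  err <- vapply(seq_along(seasons), function(s) {
    bi <- season_bloom_index(seasons[[s]]$records, tc, rc, rh)
    if (is.na(bi)) NA_real_ else bi - obs_idx[s]
  }, numeric(1))
  bloomed <- !is.na(err)
  full <- ifelse(bloomed, err, penalty)
  list(obj = sqrt(mean(full^2)),
       abias = if (any(bloomed)) abs(mean(err[bloomed])) else Inf,
       tc = tc, rc = rc, rh = rh)
}

# Coordinate descent around the grid optimum: try +/- step on each
# parameter in turn, halve all steps after a sweep with no accepted
# move, stop once every step has shrunk below `stop_frac` of its grid
# step. Parameter domain constraints (tc >= 0, rc < 0, rh > 0) are kept.
refine_optimum <- function(seasons, obs_idx, start, steps, penalty,
                           stop_frac = 0.05, max_sweeps = 200L) {
  cur <- point_objective(seasons, obs_idx, start$tc, start$rc, start$rh,
                         penalty)
  lower <- c(tc = 0, rc = -Inf, rh = .Machine$double.eps)
  upper <- c(tc = Inf, rc = -.Machine$double.eps, rh = Inf)
  step <- steps
  min_step <- stop_frac * steps
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (par in c("tc", "rc", "rh")) {
      for (dir in c(-1, 1)) {
        value <- cur[[par]] + dir * step[[par]]
        if (value < lower[[par]] || value > upper[[par]]) next
        args <- list(tc = cur$tc, rc = cur$rc, rh = cur$rh)
        args[[par]] <- value
        cand <- point_objective(seasons, obs_idx, args$tc, args$rc,
                                args$rh, penalty)
        if (candidate_better(cand, cur)) {
          cur <- cand
          moved <- TRUE
        }
      }
    }
    if (!moved) {
      step <- step / 2
      if (all(step < min_step)) break
    }
  }
  cur
}

#' Calibrate cultivar parameters against observed bloom dates
#'
#' Estimates the cultivar triple (threshold temperature `tc`, chilling
#' requirement `rc`, heating requirement `rh`) by exhaustive grid search
#' minimising the penalised RMSE between model-predicted and observed
#' peak bloom dates, optionally followed by a local coordinate-descent
#' refinement that halves the steps until they fall below 5% of the
#' grid step. The search is deterministic: ties in the objective are
#' broken by smallest absolute bias, then smallest `tc`, then `rc`
#' closest to zero, then smallest `rh`.
#'
#' @param observations tibble of observed PBD (`start_year`,
#'   `bloom_date`); at least 3 seasons must have usable weather.
#' @param weather daily weather tibble covering the observed seasons.
#' @param grid a [grid_spec()].
#' @param refine run the local refinement (default `TRUE`).
#' @param penalty days of error charged to a non-blooming season (see
#'   [penalized_rmse()]).
#' @param max_gap forwarded to [extract_season()].
#' @param trace keep the per-`tc` search trace in the result.
#' @return a `calibration_result`: list with `params` (the optimum as
#'   [chill_params()]), `objective` (penalised RMSE, days), `fit`
#'   ([evaluate_fit()] statistics over the seasons that bloom at the
#'   optimum), `n_seasons`, `seasons_used`, `seasons_dropped` (weather
#'   QC failures), `failed_at_optimum` (start years that do not bloom
#'   under the optimum), `grid`, `refined`, and optionally `trace`.
#' @examples
#' \donttest{
#' wx <- simulate_weather(n_years = 8, start_year = 2000, seed = 7)
#' truth <- chill_params(5, -20, 50)
#' obs <- simulate_pbd(wx, truth)
#' calibrate(obs, wx,
#'           grid = grid_spec(c(4, 6, 0.5), c(-30, -21, 3), c(40, 60, 5)))
#' }
#' @export
calibrate <- function(observations, weather, grid = grid_spec(),
                      refine = TRUE, penalty = 60, max_gap = 3L,
                      trace = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(observations) == 0L) {
    stop("no observations supplied", call. = FALSE)
  }
  fitdat <- assemble_fit_seasons(observations, weather, max_gap = max_gap)
  if (length(fitdat$seasons) < 3L) {
    stop("calibration needs >= 3 seasons with both weather and observed ",
         "PBD; got ", length(fitdat$seasons), call. = FALSE)
  }
  tc_vals <- grid_axis_values(grid$tc)
  rc_vals <- grid_axis_values(grid$rc)
  rh_vals <- grid_axis_values(grid$rh)
  best <- grid_search_engine(fitdat$seasons, fitdat$obs_idx, tc_vals,
                             rc_vals, rh_vals, penalty, trace = trace)
  search_trace <- best$trace
  if (refine) {
    best <- refine_optimum(fitdat$seasons, fitdat$obs_idx, best,
                           steps = c(tc = grid$tc[3], rc = grid$rc[3],
                                     rh = grid$rh[3]),
                           penalty = penalty)
  }
  params <- chill_params(best$tc, best$rc, best$rh)
  pred_idx <- vapply(fitdat$seasons, function(s) {
    season_bloom_index(s$records, params$tc, params$rc, params$rh)
  }, numeric(1))
  bloomed <- !is.na(pred_idx)
  fit <- if (any(bloomed)) {
    evaluate_fit(pred_idx[bloomed], fitdat$obs_idx[bloomed])
  } else {
    tibble(rmse = NA_real_, mae = NA_real_, bias = NA_real_,
           r2 = NA_real_, n = 0L)
  }
  structure(
    list(params = params, objective = best$obj, fit = fit,
         n_seasons = length(fitdat$seasons),
         seasons_used = fitdat$used,
         seasons_dropped = fitdat$dropped,
         failed_at_optimum = fitdat$used[!bloomed],
         grid = grid, refined = refine, trace = search_trace),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  Tc = %.3f C, Rc = %.3f chill days, Rh = %.3f anti-chill days\n",
              x$params$tc, x$params$rc, x$params$rh))
  cat(sprintf("  penalised RMSE = %.3f days over %d seasons%s\n",
              x$objective, x$n_seasons,
              if (x$refined) " (refined)" else ""))
  if (nrow(x$fit) == 1L && !is.na(x$fit$rmse)) {
    cat(sprintf("  fit (blooming seasons): RMSE %.2f, MAE %.2f, bias %.2f, r2 %s, n %d\n",
                x$fit$rmse, x$fit$mae, x$fit$bias,
                ifelse(is.na(x$fit$r2), "NA", sprintf("%.3f", x$fit$r2)),
                x$fit$n))
  }
  if (length(x$failed_at_optimum)) {
    cat("  seasons failing at optimum:",
        paste(x$failed_at_optimum, collapse = ", "), "\n")
  }
  if (nrow(x$seasons_dropped)) {
    cat("  seasons dropped (weather QC):",
        paste(x$seasons_dropped$start_year, collapse = ", "), "\n")
  }
  invisible(x)
}
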
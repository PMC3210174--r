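#' Bloom-date advancement relative to a baseline
#'
#' Days by which a projected peak bloom date precedes a baseline date,
#' computed on the non-leap day-of-year scale (positive = earlier
#' bloom). Only the month-day of each date matters.
#'
#' @param baseline,projected `Date` vectors (recycled to a common
#'   length).
#' @return numeric vector of days of advancement.
#' @examples
#' advancement(as.Date("2001-04-02"), as.Date("2001-03-22"))  # 11
#' @export
advancement <- function(baseline, projected) {
  date_to_doy(baseline) - date_to_doy(projected)
}

#' Mean advancement across cultivars
#'
#' Averages the per-cultivar advancement of projected bloom dates over
#' the cultivars present in `baselines`, for a fixed
#' location/scenario/period slice of a projection table.
#'
#' @param cells tibble with columns `cultivar` and `pbd_date`, one row
#'   per cultivar.
#' @param baselines tibble with columns `cultivar` and `pbd_date`
#'   holding the observed baseline mean bloom date of each cultivar.
#' @return mean advancement in days (positive = earlier than baseline).
#' @seealso [tidal_basin_baselines()]
#' @export
mean_advancement <- function(cells, baselines) {
  stopifnot(all(c("cultivar", "pbd_date") %in% names(cells)),
            all(c("cultivar", "pbd_date") %in% names(baselines)))
  if (anyDuplicated(cells$cultivar)) {
    stop("cells must hold one row per cultivar", call. = FALSE)
  }
  miss <- setdiff(baselines$cultivar, cells$cultivar)
  if (length(miss)) {
    stop("missing cultivar(s) in cells: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(baselines$cultivar, cells$cultivar)
  mean(advancement(baselines$pbd_date, cells$pbd_date[idx]))
}

#' Standard deviation of bloom dates across locations
#'
#' Sample standard deviation (n - 1 denominator) of the non-leap
#' day-of-year values of a set of bloom dates, the summary used for
#' cross-location spread in projection tables. Translation-invariant:
#' shifting every date by the same number of days leaves it unchanged.
#'
#' @param dates `Date` vector, `n >= 2`.
#' @return the standard deviation in days (full precision; report
#'   rounded to one decimal).
#' @export
sd_across_dates <- function(dates) {
  if (length(dates) < 2L) {
    stop("need at least 2 dates", call. = FALSE)
  }
  sd(date_to_doy(dates))
}

#' Project peak bloom dates from monthly climate normals
#'
#' For each location/scenario/period group in a monthly-normals table,
#' downscales the normals to a daily climatology
#' ([downscale_normals()]), wraps it into a normal-year dormancy season
#' ([climatology_to_season()]), and runs the two-stage chill model for
#' each cultivar. Each projected bloom date is the single model run on
#' the period's climatology (normals are run directly, not resampled
#' into synthetic years). Cells where the model fails to release or to
#' bloom are flagged in the `status` column, not dropped; bloom dates
#' outside February-June (day-of-year 32-181) are flagged `anomalous`.
#'
#' @param params a named list of [chill_params()] (names = cultivars),
#'   or a single `chill_params` object.
#' @param normals_tbl tibble as from [read_monthly_normals()]: columns
#'   `location_id`, `period`, `month`, `tmax`, `tmin`, optionally
#'   `scenario`.
#' @param baselines optional tibble (`cultivar`, `pbd_date`) of observed
#'   baseline bloom dates; when given, an `advancement_days` column is
#'   added to the cells.
#' @return a `pbd_projection`: list with `cells` (tibble: `cultivar`,
#'   `location_id`, `scenario`, `period`, `pbd_date`, `pbd_doy`,
#'   `status`, `anomalous`, and optionally `advancement_days`) and
#'   `summary` (tibble of cross-location SDs per
#'   cultivar/scenario/period, rounded to one decimal).
#' @export
project_pbd <- function(params, normals_tbl, baselines = NULL) {
  if (inherits(params, "chill_params")) {
    params <- list(cultivar = params)
  }
  stopifnot(is.list(params), length(params) >= 1L,
            !is.null(names(params)), all(nzchar(names(params))))
  for (p in params) stopifnot(inherits(p, "chill_params"))
  if (nrow(normals_tbl) == 0L) {
    stop("empty normals table", call. = FALSE)
  }
  groups <- split_normals(normals_tbl)
  rows <- list()
  for (nm in names(groups)) {
    clim <- downscale_normals(groups[[nm]])
    season <- climatology_to_season(clim)
    for (cv in names(params)) {
      pred <- run_season(season, params[[cv]])
      pbd_date <- as.Date(NA)
      pbd_doy <- NA_integer_
      if (pred$status == "bloomed") {
        # re-anchor the nominal-year date on the non-leap DOY scale
        pbd_doy <- date_to_doy(pred$bloom_date)
        pbd_date <- doy_to_date(pbd_doy)
      }
      rows[[length(rows) + 1L]] <- tibble(
        cultivar = cv, location_id = clim$location_id,
        scenario = clim$scenario, period = clim$period,
        pbd_date = pbd_date, pbd_doy = pbd_doy, status = pred$status,
        anomalous = !is.na(pbd_doy) & (pbd_doy < 32L | pbd_doy > 181L))
    }
  }
  cells <- do.call(rbind, rows)
  if (!is.null(baselines)) {
    idx <- match(cells$cultivar, baselines$cultivar)
    cells$advancement_days <- ifelse(
      is.na(idx) | is.na(cells$pbd_doy), NA_real_,
      date_to_doy(baselines$pbd_date[idx]) - cells$pbd_doy)
  }
  key <- factor(paste(cells$cultivar, cells$scenario, cells$period,
                      sep = "|"))
  summary_rows <- lapply(split(cells, key), function(g) {
    ok <- !is.na(g$pbd_date)
    tibble(cultivar = g$cultivar[1], scenario = g$scenario[1],
           period = g$period[1], n_locations = sum(ok),
           sd_days = if (sum(ok) >= 2)
             round(sd_across_dates(g$pbd_date[ok]), 1) else NA_real_)
  })
  structure(list(cells = cells, summary = do.call(rbind, summary_rows)),
            class = "pbd_projection")
}

#' @export
print.pbd_projection <- function(x, ...) {
  cat("<pbd_projection> ", nrow(x$cells), " cells\n", sep = "")
  print(x$cells)
  cat("cross-location spread:\n")
  print(x$summary)
  invisible(x)
}

#' Write a projection to CSV
#'
#' Writes the cells and summary tables of a [project_pbd()] result as
#' plain CSVs (dates in ISO-8601); reading them back with
#' `read.csv(colClasses = ...)` reproduces the tables.
#'
#' @param projection a `pbd_projection` object.
#' @param cells_path,summary_path output paths; `summary_path = NULL`
#'   skips the summary.
#' @return `cells_path`, invisibly.
#' @export
write_projection <- function(projection, cells_path, summary_path = NULL) {
  stopifnot(inherits(projection, "pbd_projection"))
  write.csv(projection$cells, cells_path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    write.csv(projection$summary, summary_path, row.names = FALSE,
              quote = FALSE)
  }
  invisible(cells_path)
}

#' Published Mid-Atlantic bloom-date projections (reference table)
#'
#' Projected mean peak bloom dates of the Yoshino and Kwanzan cherries
#' at four Mid-Atlantic locations (Washington DC; Baltimore, MD;
#' Kearneysville, WV; Richmond, VA) for the 2020s, 2050s and 2080s
#' normal periods under the A1B (MPI-ECHAM5) and A2 (CCCMA-CGCM2)
#' emissions scenarios, as published for the Tidal Basin study region.
#' Dates carry the nominal non-leap year 2001; only month-day is
#' meaningful. Shipped as a worked-example / cross-check dataset for
#' [sd_across_dates()] and [mean_advancement()].
#'
#' @return tibble with columns `cultivar`, `location_id`, `scenario`,
#'   `period`, `pbd_date`.
#' @seealso [tidal_basin_baselines()]
#' @export
mid_atlantic_pbd_table <- function() {
  path <- system.file("extdata", "mid_atlantic_projected_pbd.csv",
                      package = "bloomcast", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  tibble(cultivar = raw$cultivar, location_id = raw$location_id,
         scenario = raw$scenario, period = raw$period,
         pbd_date = as.Date(raw$pbd_date))
}

#' Observed Tidal Basin baseline bloom dates (1971-2000 means)
#'
#' Observed mean peak bloom dates at the Tidal Basin over the 1971-2000
#' normal period: April 2 for Yoshino, April 15 for Kwanzan (nominal
#' non-leap year 2001).
#'
#' @return tibble with columns `cultivar` and `pbd_date`.
#' @export
tidal_basin_baselines <- function() {
  tibble(cultivar = c("Yoshino", "Kwanzan"),
         pbd_date = as.Date(c("2001-04-02", "2001-04-15")))
}
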
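test_that("day-of-year arithmetic follows the non-leap convention", {
  expect_equal(date_to_doy(as.Date("2001-01-01")), 1L)
  expect_equal(date_to_doy(as.Date("2001-03-27")), 86L)
  expect_equal(date_to_doy(as.Date("2001-04-02")), 92L)
  # month-day is what counts: a leap-year date maps to the same DOY
  expect_equal(date_to_doy(as.Date("2000-04-02")), 92L)
  expect_equal(date_to_doy(as.Date("2000-04-02"), leap = TRUE), 93L)
  expect_equal(doy_to_date(92), as.Date("2001-04-02"))

  expect_equal(advancement(as.Date("2001-04-02"), as.Date("2001-04-02")), 0L)
  expect_equal(advancement(as.Date("2001-04-02"), as.Date("2001-03-22")), 11L)
  expect_equal(advancement(as.Date("2001-04-15"), as.Date("2001-04-06")), 9L)
})

test_that("cross-cultivar and cross-location summaries behave", {
  base <- tidal_basin_baselines()
  cells <- tibble::tibble(
    cultivar = c("Yoshino", "Kwanzan"),
    pbd_date = as.Date(c("2001-03-27", "2001-04-11")))
  expect_equal(mean_advancement(cells, base), 5)
  # single cultivar: its own advancement
  expect_equal(mean_advancement(cells[1, ], base[1, ]), 6)
  expect_error(mean_advancement(cells[1, ], base), "missing cultivar")

  same <- as.Date(rep("2001-04-02", 3))
  expect_equal(sd_across_dates(same), 0)
  expect_error(sd_across_dates(same[1]), "at least 2")
  # translation invariance
  withr::local_seed(5)
  d <- as.Date("2001-03-01") + sample(0:40, 6)
  for (k in c(-10, 3, 17)) {
    expect_equal(sd_across_dates(d + k), sd_across_dates(d))
  }
})

test_that("projection runs the model per cell and summarises spread", {
  tbl <- rbind(dc_like_normals_tbl("site-a", "2020s", "A1B"),
               dc_like_normals_tbl("site-b", "2020s", "A1B"))
  params <- list(Yoshino = yoshino_params())
  proj <- project_pbd(params, tbl)
  expect_s3_class(proj, "pbd_projection")
  expect_equal(nrow(proj$cells), 2L)
  expect_equal(proj$cells$status, rep("bloomed", 2))

  # a cell equals the hand-assembled pipeline on the same normals
  nm <- split_normals(dc_like_normals_tbl("site-a", "2020s", "A1B"))[[1]]
  by_hand <- run_season(climatology_to_season(downscale_normals(nm)),
                        params$Yoshino)
  expect_equal(proj$cells$pbd_doy[proj$cells$location_id == "site-a"],
               date_to_doy(by_hand$bloom_date))
  expect_false(any(proj$cells$anomalous))

  # identical locations -> zero cross-location spread
  expect_equal(proj$summary$sd_days, 0)
  expect_equal(proj$summary$n_locations, 2L)

  # baselines add an advancement column
  proj2 <- project_pbd(params, tbl, baselines = tidal_basin_baselines())
  expect_equal(proj2$cells$advancement_days,
               rep(92 - proj2$cells$pbd_doy[1], 2))

  # failing cells are flagged, not dropped
  cold <- dc_like_normals_tbl("freezer", "2020s", "A1B")
  cold$tmax <- cold$tmax - 40
  cold$tmin <- cold$tmin - 40
  proj3 <- project_pbd(params, cold)
  expect_equal(nrow(proj3$cells), 1L)
  expect_true(proj3$cells$status %in% c("no-release", "no-bloom"))
  expect_true(is.na(proj3$cells$pbd_date))

  expect_error(project_pbd(params, tbl[0, ]), "empty normals")
})

test_that("warming the spring months never delays the projected bloom", {
  params <- list(Yoshino = yoshino_params())
  base <- project_pbd(params, dc_like_normals_tbl())
  expect_equal(base$cells$status, "bloomed")
  prev <- base$cells$pbd_doy
  for (delta in c(0.5, 1, 2, 4)) {
    warmed <- project_pbd(params, dc_like_normals_tbl(spring_delta = delta))
    expect_equal(warmed$cells$status, "bloomed")
    expect_lte(warmed$cells$pbd_doy, prev)
    prev <- warmed$cells$pbd_doy
  }
})

test_that("projection tables survive a CSV round trip", {
  dir <- withr::local_tempdir()
  tbl <- rbind(dc_like_normals_tbl("site-a", "2020s", "A1B"),
               dc_like_normals_tbl("site-b", "2020s", "A1B"))
  tbl$tmax[tbl$location_id == "site-b"] <-
    tbl$tmax[tbl$location_id == "site-b"] + 1
  tbl$tmin[tbl$location_id == "site-b"] <-
    tbl$tmin[tbl$location_id == "site-b"] + 1
  proj <- project_pbd(list(Yoshino = yoshino_params(),
                           Kwanzan = chill_params(5.3, -114, 289.1)), tbl)
  cells_path <- file.path(dir, "cells.csv")
  summary_path <- file.path(dir, "summary.csv")
  write_projection(proj, cells_path, summary_path)
  back <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(proj$cells))
  expect_equal(back$cultivar, proj$cells$cultivar)
  expect_equal(as.Date(back$pbd_date), proj$cells$pbd_date)
  expect_equal(back$pbd_doy, proj$cells$pbd_doy)
  sm <- utils::read.csv(summary_path, stringsAsFactors = FALSE)
  expect_equal(sm$sd_days, proj$summary$sd_days)
})
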
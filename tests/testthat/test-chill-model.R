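test_that("daily contributions match the closed-form cases", {
  # case 1: whole triangle above the threshold
  r <- chill_day(14, 6, 4.3)
  expect_equal(r$case, "1")
  expect_equal(r$cd, 0)
  expect_equal(r$ca, 10 - 4.3)

  # case 3: whole triangle between 0 and the threshold
  r <- chill_day(4, 0, 5.3)
  expect_equal(r$case, "3")
  expect_equal(r$cd, -2)
  expect_equal(r$ca, 0)

  # case 2 and case 4 against the triangle-integration oracle
  r <- chill_day(10, 0, 4.3)
  expect_equal(r$case, "2")
  oracle <- tri_oracle(10, 0, 4.3)
  expect_equal(r$cd, unname(oracle["cd"]), tolerance = 1e-5)
  expect_equal(r$ca, unname(oracle["ca"]), tolerance = 1e-5)
  expect_equal(r$ca, (10 - 4.3)^2 / 20)

  r <- chill_day(4, -4, 5)
  expect_equal(r$case, "4")
  oracle <- tri_oracle(4, -4, 5)
  expect_equal(r$cd, unname(oracle["cd"]), tolerance = 1e-5)
  expect_equal(r$cd, -1)
  expect_equal(r$ca, 0)

  # case 5 straddles both 0 and the threshold
  r <- chill_day(8, -2, 5)
  expect_equal(r$case, "5")
  oracle <- tri_oracle(8, -2, 5)
  expect_equal(r$cd, unname(oracle["cd"]), tolerance = 1e-5)
  expect_equal(r$ca, unname(oracle["ca"]), tolerance = 1e-5)

  # degenerate days
  expect_equal(chill_day(-3, -8, 5)$case, "subzero")
  expect_equal(chill_day(-3, -8, 5)$ca, 0)
  iso <- chill_day(7, 7, 5)
  expect_equal(iso$case, "isothermal")
  expect_equal(iso$ca, 2)
  expect_equal(iso$cd, 0)
  expect_equal(chill_day(3, 3, 5)$ca, 0)

  expect_error(chill_day(5, 9, 4.3), "tmax < tmin")
})

test_that("signs and the case partition hold over random inputs", {
  withr::local_seed(421)
  n <- 2000
  tmin <- runif(n, -25, 20)
  tmax <- tmin + runif(n, 1e-3, 25)
  tc <- runif(n, 0, 12)
  for (i in seq_len(n)) {
    r <- chill_day(tmax[i], tmin[i], tc[i])
    expect_lte(r$cd, 0)
    expect_gte(r$ca, 0)
    if (tmax[i] >= 0) {
      p <- c(`1` = tmin[i] >= tc[i],
             `2` = tmin[i] >= 0 && tmin[i] <= tc[i] && tmax[i] > tc[i],
             `3` = tmin[i] >= 0 && tmax[i] <= tc[i],
             `4` = tmin[i] < 0 && tmax[i] <= tc[i],
             `5` = tmin[i] < 0 && tmax[i] > tc[i])
      expect_equal(sum(p), 1L)
      expect_equal(r$case, names(p)[p])
    } else {
      expect_equal(r$case, "subzero")
    }
  }
})

test_that("contributions are continuous across case boundaries", {
  withr::local_seed(99)
  eps <- 1e-6
  jitter <- expand.grid(dx = c(-eps, 0, eps), dn = c(-eps, 0, eps))
  check_boundary <- function(tmax, tmin, tc) {
    vals <- mapply(function(dx, dn) {
      r <- chill_day(tmax + dx, tmin + dn, tc)
      c(r$cd, r$ca)
    }, jitter$dx, jitter$dn)
    expect_lt(max(vals[1, ]) - min(vals[1, ]), 1e-4)
    expect_lt(max(vals[2, ]) - min(vals[2, ]), 1e-4)
  }
  for (i in 1:40) {
    tc <- runif(1, 1, 10)
    check_boundary(tc + runif(1, 1, 10), tc, tc)        # case 1 | 2
    check_boundary(tc, runif(1, 0, tc - 0.5), tc)       # case 2 | 3
    check_boundary(runif(1, 0.5, tc), 0, tc)            # case 3 | 4
    check_boundary(tc + runif(1, 1, 10), 0, tc)         # case 2 | 5
    check_boundary(tc, runif(1, -10, -0.5), tc)         # case 4 | 5
    check_boundary(0, runif(1, -10, -0.5), tc)          # case 4 | subzero
  }
})

test_that("run_season accumulates chill then forcing sequentially", {
  # 30 cold days at (4, 2) then warm days at (14, 6); Tc = 5 gives
  # Cd = -1/day, release on day 20 under Rc = -20; forcing restarts the
  # next day with Ca = 0 until the warm phase, then 5/day to Rh = 50.
  wx <- step_weather(2009, n_cold = 30)
  season <- extract_season(wx, 2009)
  pred <- run_season(season, chill_params(5, -20, 50))
  expect_equal(pred$status, "bloomed")
  expect_equal(pred$release_date, as.Date("2009-10-20"))
  expect_equal(pred$bloom_date, as.Date("2009-10-01") + 39)  # day 40

  # trajectory invariants and conservation
  tr <- pred$trajectory
  expect_true(all(diff(tr$dc) <= 1e-12))
  expect_true(all(diff(tr$dh) >= -1e-12))
  ri <- match(pred$release_date, tr$date)
  expect_equal(tr$dh[ri], 0)  # forcing starts the day after release
  expect_equal(tr$dc[nrow(tr)], sum(tr$cd[1:ri]))
  expect_equal(tr$dh[nrow(tr)], sum(tr$ca[(ri + 1):nrow(tr)]))

  # all-warm season never accumulates chill
  warm <- run_season(extract_season(constant_weather(2009, 20, 12), 2009),
                     chill_params(5, -20, 50))
  expect_equal(warm$status, "no-release")
  expect_true(is.na(warm$bloom_date))
  expect_true(all(warm$trajectory$dh == 0))

  # chilling satisfied but forcing never reached
  cold <- run_season(extract_season(constant_weather(2009, 4, 2), 2009),
                     chill_params(5, -20, 50))
  expect_equal(cold$status, "no-bloom")
  expect_equal(cold$release_date, as.Date("2009-10-20"))
  expect_true(is.na(cold$bloom_date))

  # parameter invariants enforced at construction
  expect_error(chill_params(5, -20, 0), "rh must be")
  expect_error(chill_params(5, 20, 50), "rc must be")
  expect_error(chill_params(-1, -20, 50), "tc must be")
})

test_that("predict_pbd handles many seasons and reports QC failures", {
  p <- chill_params(5, -20, 50)
  wx <- rbind(step_weather(2008, n_cold = 30), step_weather(2009, n_cold = 30))
  preds <- predict_pbd(wx, p)
  expect_equal(nrow(preds), 2L)
  expect_equal(preds$status, c("bloomed", "bloomed"))
  # seasons are independent: both equal the single-season run
  single <- run_season(extract_season(wx, 2009), p)
  expect_equal(preds$bloom_date[preds$start_year == 2009],
               single$bloom_date)
  expect_equal(format(preds$bloom_date[1], "%m-%d"),
               format(preds$bloom_date[2], "%m-%d"))

  # a season with missing February is flagged, the other predicted
  holey <- wx[!(wx$date >= as.Date("2010-02-01") &
                  wx$date <= as.Date("2010-02-28")), ]
  preds <- predict_pbd(holey, p, start_years = c(2008, 2009))
  expect_equal(preds$status[preds$start_year == 2009], "weather-rejected")
  expect_equal(preds$status[preds$start_year == 2008], "bloomed")
  expect_equal(attr(preds, "failures")$start_year, 2009L)

  expect_error(predict_pbd(wx[1:10, ], p), "does not fully cover")
})

test_that("uniform warming after release never delays bloom", {
  p <- yoshino_params()
  for (seed in 1:4) {
    wx <- simulate_weather(n_years = 1, start_year = 2002, seed = seed)
    base <- run_season(extract_season(wx, 2002), p)
    expect_equal(base$status, "bloomed")
    for (delta in c(0.5, 1, 3)) {
      warmed <- wx
      after <- warmed$date > base$release_date
      warmed$tmax[after] <- warmed$tmax[after] + delta
      warmed$tmin[after] <- warmed$tmin[after] + delta
      shifted <- run_season(extract_season(warmed, 2002), p)
      expect_equal(shifted$release_date, base$release_date)
      expect_equal(shifted$status, "bloomed")
      expect_lte(as.numeric(shifted$bloom_date - base$bloom_date), 0)
    }
  }
})
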
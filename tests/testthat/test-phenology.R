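test_that("sigmoid forcing terms match scalar evaluations", {
  w <- flat_weather("2009-10-01", "2010-06-30", T = 15)
  p <- start_forcing_params("02-01", -0.25, 15)
  # single day with tavg = c contributes exactly 0.5
  expect_equal(sigmoid_forcing_sum(w, 2010, p, 32), 0.5)

  w2 <- flat_weather("2009-10-01", "2010-06-30", T = 25)
  expect_equal(sigmoid_forcing_sum(w2, 2010, p, 32), 1 / (1 + exp(-2.5)))

  # far below the threshold the contribution saturates at ~0
  w3 <- flat_weather("2009-10-01", "2010-06-30", T = -85)
  expect_lt(sigmoid_forcing_sum(w3, 2010, p, 36), 5e-10)

  # accumulation crosses the year boundary for autumn onsets
  pa <- start_forcing_params("12-30", -0.25, 15)
  expect_equal(sigmoid_forcing_sum(w, 2010, pa, 2), 4 * 0.5)
})

test_that("heat sums clamp negative contributions and honour the trigger", {
  Tv <- c(rep(5, 59), 12, 10, 15, rep(30, 120))  # doy 60, 61, 62 = 12, 10, 15
  w <- flat_weather("2010-01-01", "2010-06-30", T = Tv[1:181])
  p <- peak_heat_params(T_D = 12, Th = 11)
  # trigger fires on doy 60; contributions 1 + 0 + 4
  expect_equal(heat_sum(w, 2010, p, 59, 62), 5)
  # all days below the base: zero
  expect_equal(heat_sum(w, 2010, peak_heat_params(0, 40), 59, 62), 0)
  # zero base sums the temperatures themselves
  w2 <- flat_weather("2010-01-01", "2010-06-30", T = c(rep(0, 59), 1, 2, 3,
                                                       rep(0, 119)))
  expect_equal(heat_sum(w2, 2010, peak_heat_params(1, 0), 59, 62), 6)
  # trigger never reached: zero
  expect_equal(heat_sum(w, 2010, peak_heat_params(40, 0), 59, 62), 0)
})

test_that("forcing sums are monotone and bounded", {
  ds <- noiseless_dataset()
  p <- start_forcing_params("01-15", -0.5, 12)
  sums <- vapply(seq(40, 120, by = 10), function(doy)
    sigmoid_forcing_sum(ds$weather, 2010, p, doy), 0)
  expect_true(all(diff(sums) > 0))
  # each daily term lies in (0, 1): the sum over n days is < n
  expect_lt(sums[length(sums)], 120 + 31 + 30 + 31 - 14)
  # raising any day's temperature raises the sum (d < 0)
  warm <- ds$weather
  warm$T <- warm$T + 2
  expect_gt(sigmoid_forcing_sum(warm, 2010, p, 90),
            sigmoid_forcing_sum(ds$weather, 2010, p, 90))
  # heat sum is non-negative and non-decreasing in until_doy
  hp <- peak_heat_params(15, 8)
  hs <- vapply(seq(70, 130, by = 10), function(doy)
    heat_sum(ds$weather, 2010, hp, 65, doy), 0)
  expect_true(all(hs >= 0))
  expect_true(all(diff(hs) >= 0))
})

test_that("the default grids span the documented search spaces", {
  g <- phenology_grid("start")
  expect_equal(length(g$F1), 151)   # 1 Oct .. 28 Feb
  expect_equal(length(g$d), 40)     # -10 .. -0.25 by 0.25, zero excluded
  expect_true(all(g$d < 0))
  expect_equal(length(g$c), 41)     # 0 .. 40 degC
  expect_equal(prod(lengths(g)), 247640)
  gp <- phenology_grid("peak")
  expect_equal(prod(lengths(gp)), 41 * 41)
})

test_that("grid calibration agrees with an independent brute-force oracle", {
  toy <- toy_calibration_case()
  grid <- list(F1 = c("01-20", "02-01", "02-10"), d = c(-0.5, -0.25),
               c = c(10, 15))
  cands <- candidate_grid(toy$weather, toy$seasons, "start", "5", 2004:2006,
                          grid = grid)
  oracle <- brute_start_candidates(toy$weather, toy$seasons, grid)
  expect_equal(nrow(cands), nrow(oracle))
  expect_equal(cands$M, oracle$M)
  expect_equal(cands$sd, oracle$sd)
  expect_equal(cands$rsd, oracle$rsd)
  expect_equal(cands$train_mae, oracle$train_mae)
  sel <- select_params(cands)
  osel <- oracle[order(oracle$train_mae, oracle$rsd)[1], ]
  expect_equal(sel[c("F1", "d", "c", "M")], osel[c("F1", "d", "c", "M")])

  # peak mode against the same style of oracle
  gridp <- list(T_D = c(12, 15), Th = c(8, 10))
  candp <- candidate_grid(toy$weather, toy$seasons, "peak", "5", 2004:2006,
                          grid = gridp)
  oraclep <- brute_peak_candidates(toy$weather, toy$seasons, gridp)
  expect_equal(nrow(candp), nrow(oraclep))
  expect_equal(candp$M, oraclep$M)
  expect_equal(candp$train_mae, oraclep$train_mae)
})

test_that("filters drop zero-forcing and inconsistent candidates", {
  ds <- noiseless_dataset()
  sea <- season_dates(ds$pollen)
  grid <- list(F1 = c("01-25", "02-05"), d = c(-0.25, -2), c = c(15, 40))
  cands <- candidate_grid(ds$weather, sea, "start", "5", 2004:2015,
                          grid = grid)
  # c = 40 on temperate data accumulates ~nothing before the start day
  expect_false(any(cands$c == 40 & cands$d == -2))
  expect_true(all(cands$M > 1e-6))
  expect_true(all(cands$rsd <= 50))
})

test_that("excluding the start day lowers every candidate's units", {
  toy <- toy_calibration_case()
  grid <- list(F1 = c("01-20", "02-01"), d = c(-0.5), c = c(10, 15))
  inc <- candidate_grid(toy$weather, toy$seasons, "start", "5", 2004:2006,
                        grid = grid, compute_mae = FALSE)
  exc <- candidate_grid(toy$weather, toy$seasons, "start", "5", 2004:2006,
                        grid = grid, compute_mae = FALSE,
                        include_start_day = FALSE)
  m <- merge(inc, exc, by = c("F1", "d", "c"))
  expect_true(all(m$M.y < m$M.x))
})

test_that("candidate selection breaks ties by RSD then grid order", {
  t1 <- tibble::tibble(T_D = c(10, 11, 12), Th = c(1, 2, 3),
                       M = c(5, 6, 7), sd = 1,
                       rsd = c(20, 10, 10), train_mae = c(2, 3, 2))
  expect_equal(select_params(t1)$T_D, 12)  # unique min MAE with lower rsd
  t1$train_mae <- c(2, 2, 2)
  expect_equal(select_params(t1)$T_D, 11)  # rsd tie-break
  t1$rsd <- c(10, 10, 10)
  expect_equal(select_params(t1)$T_D, 10)  # grid order
  expect_error(select_params(t1[0, ]), "no candidate")
})

test_that("phenological prediction crosses the requirement exactly", {
  w <- flat_weather("2009-10-01", "2010-06-30", T = 15)
  p <- start_forcing_params("02-01", -0.25, 15)  # each day contributes 0.5
  # requirement 9.5 * 0.5: first crossing on the 10th day after onset
  expect_equal(predict_day_phenology(p, w, 2010, M = 9.5 * 0.5),
               day_of_year(as.Date("2010-02-10")))
  expect_error(predict_day_phenology(p, w, 2010, M = 1e6), "no crossing")

  hp <- peak_heat_params(15, 10)  # 5 heat units per day at T = 15
  expect_equal(predict_day_phenology(hp, w, 2010, start_day = 60, M = 14.5),
               63)  # trigger on day 61; cumulative heat 5, 10, 15
  expect_error(predict_day_phenology(hp, w, 2010, start_day = 60, M = 1e6),
               "no crossing")

  # w_obs = 1 blending is a no-op
  ds <- noiseless_dataset()
  cal <- start_forcing_params("01-31", -1, 15)
  expect_identical(
    predict_day_phenology(cal, ds$weather, 2016, M = 12,
                          blend = blend_config(w_obs = 1),
                          training_years = 2004:2015),
    predict_day_phenology(cal, ds$weather, 2016, M = 12))
  # uniform warming never delays the predicted day
  warm <- ds$weather
  warm$T <- warm$T + 2
  expect_lte(predict_day_phenology(cal, warm, 2016, M = 12),
             predict_day_phenology(cal, ds$weather, 2016, M = 12))
})
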
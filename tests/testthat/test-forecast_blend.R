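test_that("window enumeration is the Cartesian product of the ranges", {
  w <- enumerate_windows()
  expect_equal(nrow(w), 616)  # 56 start dates x 11 end dates
  expect_equal(length(unique(w$start_md)), 56)
  expect_equal(length(unique(w$end_md)), 11)

  w1 <- enumerate_windows(c("02-01", "02-01"), c("03-01", "03-01"))
  expect_equal(nrow(w1), 1)

  wp <- enumerate_windows(end_range = "mps-start")
  expect_equal(nrow(wp), 56)
  expect_true(all(is.na(wp$end_md)))

  # |A x B| always
  for (ranges in list(list(c("01-05", "01-09"), c("02-01", "02-03")),
                      list(c("01-31", "02-02"), c("03-10", "03-11")))) {
    a <- length(pollenseason:::md_seq(ranges[[1]][1], ranges[[1]][2]))
    b <- length(pollenseason:::md_seq(ranges[[2]][1], ranges[[2]][2]))
    expect_equal(nrow(enumerate_windows(ranges[[1]], ranges[[2]])), a * b)
  }
  expect_error(enumerate_windows(c("01-01", "03-05"), c("03-01", "03-11")),
               "strictly before")
})

test_that("blended values follow the 80/20 rule after the issue date", {
  w <- flat_weather("2009-01-01", "2010-12-31", T = 10)
  w$T[w$date == as.Date("2010-03-01")] <- 20

  # on/before the issue date: observed value untouched
  expect_equal(blended_value(w, 2010, "02-10", "T", blend_config(), 2009), 10)
  # after: 0.8 * 20 + 0.2 * 10
  expect_equal(blended_value(w, 2010, "03-01", "T", blend_config(), 2009), 18)
  # degenerate weight: pure climatology
  expect_equal(blended_value(w, 2010, "03-01", "T",
                             blend_config(w_obs = 0), 2009), 10)
  # convex combination bounds on random cases
  set.seed(7)
  for (i in 1:15) {
    obs <- runif(1, -5, 30)
    hist <- runif(1, -5, 30)
    w2 <- w
    w2$T[w2$date == as.Date("2010-03-01")] <- obs
    w2$T[w2$date == as.Date("2009-03-01")] <- hist
    b <- blended_value(w2, 2010, "03-01", "T",
                       blend_config(w_obs = runif(1)), 2009)
    expect_gte(b, min(obs, hist) - 1e-12)
    expect_lte(b, max(obs, hist) + 1e-12)
  }
})

test_that("window feature vectors are per-variable means over the window", {
  w <- flat_weather("2010-01-01", "2010-03-31", T = 10)
  w$T[w$date == as.Date("2010-02-01")] <- 10
  w$T[w$date == as.Date("2010-02-02")] <- 14
  x <- window_feature_vector(w, 2010, "02-01", "02-02")
  expect_equal(x[["T"]], 12)
  expect_equal(names(x), c("T", "H", "Rf", "Cc", "Sd", "Ws", "Wd", "Wg"))

  # 1-day window returns the day's record verbatim
  x1 <- window_feature_vector(w, 2010, "02-02", "02-02")
  expect_equal(unname(x1), c(14, 50, 0, 40, 6, 5, 180, 9))

  # blending with an issue date after the window end changes nothing
  wz <- flat_weather("2009-01-01", "2010-12-31",
                     T = sin(1:730), H = 50 + 10 * cos(1:730))
  a <- window_feature_vector(wz, 2010, "01-15", "02-20")
  b <- window_feature_vector(wz, 2010, "01-15", "02-20",
                             blend = blend_config("02-25"),
                             training_years = 2009)
  expect_equal(a, b)
})

test_that("leap day is excluded from window aggregation", {
  w <- flat_weather("2008-01-01", "2008-03-31", T = 10)
  w$T[w$date == as.Date("2008-02-29")] <- 1000
  x <- window_feature_vector(w, 2008, "02-28", "03-01")
  expect_equal(x[["T"]], 10)
})

test_that("blending handles a window with a single post-issue day", {
  w <- flat_weather("2009-01-01", "2010-12-31", T = 10)
  w$T[w$date == as.Date("2010-02-26")] <- 20
  x <- window_feature_vector(w, 2010, "02-20", "02-26",
                             blend = blend_config("02-25"),
                             training_years = 2009)
  # six observed days at 10 plus one blended day 0.8*20 + 0.2*10 = 18
  expect_equal(x[["T"]], (6 * 10 + 18) / 7)
})

test_that("w_obs = 1 makes the blended pipeline equal the observed one", {
  ds <- noisy_dataset()
  model <- example_model("start_5")
  for (y in 2016:2017) {
    expect_identical(
      predict_day(model, ds$weather, y, blend = blend_config(w_obs = 1),
                  training_years = 2004:2015),
      predict_day(model, ds$weather, y))
  }
})
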
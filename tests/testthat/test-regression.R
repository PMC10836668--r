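test_that("OLS fit matches closed-form solutions and the degenerate contract", {
  X <- cbind(x = c(1, 2, 3))
  f <- fit_linear(X, c(2, 4, 6))
  expect_equal(f$a, 0)
  expect_equal(unname(f$b), 2)
  expect_equal(f$r2, 1)

  # slope = cov/var = 1.5, intercept = 7/6
  f2 <- fit_linear(cbind(x = c(0, 1, 2)), c(1, 3, 4))
  expect_equal(unname(f2$b), 1.5)
  expect_equal(f2$a, 7 / 6)

  f3 <- fit_linear(cbind(x = c(0, 1, 2)), c(5, 5, 5))
  expect_equal(unname(f3$b), 0)
  expect_equal(f3$r2, 0)
  expect_equal(f3$p_value, 1)

  expect_error(fit_linear(cbind(x = c(1, 1, 1)), c(1, 2, 3)),
               "rank-deficient")
  expect_error(fit_linear(cbind(x = 1:3, z = c(2, 4, 6)), c(1, 2, 3)),
               "too few years")
  # agrees with lm() on a generic case
  set.seed(1)
  X4 <- cbind(a = rnorm(10), b = rnorm(10))
  y4 <- 2 + X4 %*% c(1, -3) + rnorm(10, 0, 0.3)
  f4 <- fit_linear(X4, as.numeric(y4))
  ref <- summary(lm(y4 ~ X4))
  expect_equal(f4$adj_r2, ref$adj.r.squared)
  expect_equal(unname(f4$p_value),
               unname(pf(ref$fstatistic[1], ref$fstatistic[2],
                         ref$fstatistic[3], lower.tail = FALSE)))
})

test_that("forward stepwise selects signal, drops noise, and breaks ties by order", {
  set.seed(3)
  x1 <- rnorm(12)
  x2 <- rnorm(12)
  X <- cbind(x1 = x1, x2 = x2)
  st <- forward_stepwise(X, x1)  # response is exactly x1
  expect_equal(st$variables, "x1")

  # single candidate: identical to the simple regression
  st1 <- forward_stepwise(cbind(x1 = x1), 2 * x1 + 1)
  expect_equal(st1$fit$a, fit_linear(cbind(x1 = x1), 2 * x1 + 1)$a)

  # byte-identical candidates: first in declared order wins
  Xd <- cbind(u = x1, v = x1)
  std <- forward_stepwise(Xd, x1 + rnorm(12, 0, 0.1), candidates = c("u", "v"))
  expect_equal(std$variables[1], "u")
})

test_that("stepwise agrees with exhaustive best-subset search on orthogonal designs", {
  set.seed(9)
  n <- 12
  # centred orthonormal columns: orthogonal to each other and the intercept
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 4), n), center = TRUE, scale = FALSE)))
  colnames(Q) <- paste0("q", 1:4)
  adj_r2_of <- function(vars, y) fit_linear(Q[, vars, drop = FALSE], y)$adj_r2
  for (i in 1:5) {
    y <- Q %*% rnorm(4, 0, c(3, 2, 1, 0.1)) + rnorm(n, 0, 0.5)
    y <- as.numeric(y)
    st <- forward_stepwise(Q, y)
    # exhaustive search over all non-empty subsets
    subsets <- unlist(lapply(1:4, function(k)
      combn(colnames(Q), k, simplify = FALSE)), recursive = FALSE)
    scores <- vapply(subsets, adj_r2_of, 0, y = y)
    best <- subsets[[which.max(scores)]]
    expect_setequal(st$variables, best)
    # the built-in exhaustive comparison mode agrees too
    ex <- forward_stepwise(Q, y, exhaustive = TRUE)
    expect_setequal(ex$variables, best)
    expect_equal(ex$fit$adj_r2, max(scores))
  }
})

test_that("LOOCV matches a hand-enumerated 3-fold oracle", {
  # x = (0, 1, 2), y = (0, 1, 3): folds give b = 2, 1.5, 1 and a = -1, 0, 0
  X <- cbind(x = c(0, 1, 2))
  cv <- loocv_average(X, c(0, 1, 3), years = 2001:2003)
  expect_equal(unname(cv$b), 1.5)        # mean(2, 1.5, 1)
  expect_equal(cv$a, -1 / 3)             # mean(-1, 0, 0)
  # rounded out-of-fold predictions -1, 2, 2 give absolute errors 1, 1, 1
  expect_equal(cv$mae, 1)
  expect_equal(cv$folds$predicted, c(-1, 2, 2))
})

test_that("LOOCV agrees with an lm()-based fold loop and ignores year order", {
  set.seed(21)
  X <- cbind(a = rnorm(8), b = rnorm(8))
  y <- round(70 + X %*% c(2, -1) + rnorm(8))
  y <- as.numeric(y)
  cv <- loocv_average(X, y, years = 2001:2008)
  # independent oracle: lm per fold
  coefs <- t(sapply(1:8, function(i) coef(lm(y[-i] ~ X[-i, ]))))
  preds <- sapply(1:8, function(i)
    round(sum(coef(lm(y[-i] ~ X[-i, ])) * c(1, X[i, ]))))
  expect_equal(unname(cv$a), unname(mean(coefs[, 1])))
  expect_equal(unname(cv$b), unname(colMeans(coefs)[2:3]))
  expect_equal(cv$mae, mean(abs(preds - y)))
  # permuting the years leaves coefficients and MAE unchanged
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  cvp <- loocv_average(X[perm, ], y[perm], years = (2001:2008)[perm])
  expect_equal(cvp$a, cv$a)
  expect_equal(cvp$b, cv$b)
  expect_equal(cvp$mae, cv$mae)

  expect_error(loocv_average(cbind(x = 1:2), 1:2, years = 1:2),
               "at least 3")
})

test_that("noiseless exact relations give identical folds and zero MAE", {
  X <- cbind(x = c(1, 3, 4, 7, 9))
  y <- 10 + 2 * c(1, 3, 4, 7, 9)
  cv <- loocv_average(X, y, years = 1:5)
  expect_equal(cv$a, 10)
  expect_equal(unname(cv$b), 2)
  expect_equal(cv$mae, 0)
})

test_that("window search recovers a planted noiseless window with zero error", {
  ds <- noiseless_dataset()
  years <- 2004:2015
  resp <- vapply(years, function(y) {
    x <- window_feature_vector(ds$weather, y, "02-01", "03-03")
    round(130 - 4.5 * x[["T"]])
  }, 0)
  sea <- tibble::tibble(year = years, start_doy_5 = resp,
                        start_doy_2_5 = resp, peak_doy = resp + 4)
  ws <- search_best_window(ds$weather, sea, "start", "5", years,
                           start_range = c("01-25", "02-10"),
                           end_range = c("03-01", "03-05"))
  expect_lte(ws$best$loocv_mae, 0.51)
  expect_true("T" %in% ws$best$variables)
  # selected window overlaps the planted 02-01..03-03 window
  expect_lte(pollenseason:::md_num(ws$best$window$start_md),
             pollenseason:::md_num("03-03"))
  expect_gte(pollenseason:::md_num(ws$best$window$end_md),
             pollenseason:::md_num("02-01"))
  expect_equal(nrow(ws$results), 17 * 5)
})

test_that("peak-mode search skips windows starting after a season start", {
  ds <- noiseless_dataset()
  years <- 2004:2009
  sea <- season_dates(ds$pollen)
  sea$start_doy_5[sea$year == 2005] <- 50  # season already under way 19 Feb
  ws <- search_best_window(ds$weather, sea, "peak", "5", years,
                           start_range = c("02-15", "02-25"))
  expect_true(all(pollenseason:::md_num(ws$results$start_md) <=
                    pollenseason:::md_num("02-19")))
  expect_s3_class(ws$best, "pollen_lm")
})

test_that("pure-noise responses leave no admissible model", {
  ds <- noiseless_dataset()
  years <- 2004:2015
  set.seed(1234)
  resp <- sample(60:90, length(years), replace = TRUE)
  sea <- tibble::tibble(year = years, start_doy_5 = resp,
                        start_doy_2_5 = resp, peak_doy = resp + 4)
  expect_error(
    search_best_window(ds$weather, sea, "start", "5", years,
                       start_range = c("02-05", "02-09"),
                       end_range = c("03-01", "03-03")),
    "no admissible model")
})

test_that("published coefficient sets load and evaluate through prediction", {
  expect_setequal(example_model(),
                  c("start_5", "start_2_5", "peak_5", "peak_2_5"))
  m <- example_model("start_5")
  expect_s3_class(m, "pollen_lm")
  expect_equal(m$a, 177.358)
  # zero weather over the model window evaluates to the rounded intercept
  w0 <- flat_weather("2010-01-01", "2010-03-31", T = 0, H = 0, Rf = 0,
                     Cc = 0, Sd = 0, Ws = 0, Wd = 0, Wg = 0)
  expect_equal(predict_day(m, w0, 2010), 177L)
  # intermediate values round to the nearest day: shift T so the linear
  # predictor lands at 67.4
  wT <- w0
  wT$T <- (177.358 - 67.4) / 4.409
  expect_equal(predict_day(m, wT, 2010), 67L)
})

test_that("model JSON round-trips through write_model/read_model", {
  ds <- noiseless_dataset()
  years <- 2004:2015
  sea <- season_dates(ds$pollen)
  ws <- search_best_window(ds$weather, sea, "start", "5", years,
                           start_range = c("02-08", "02-12"),
                           end_range = c("03-01", "03-03"))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(ws$best, f)
  m2 <- read_model(f)
  expect_equal(m2$b, ws$best$b)
  expect_equal(m2$window$start_md, ws$best$window$start_md)
  expect_equal(predict_day(m2, ds$weather, 2016),
               predict_day(ws$best, ds$weather, 2016))
})
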
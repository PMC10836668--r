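# Shared fixtures, built in code.

# A valid weather table with constant (or supplied) values per variable.
flat_weather <- function(from, to, T = 15, H = 50, Rf = 0, Cc = 40, Sd = 6,
                         Ws = 5, Wd = 180, Wg = 9) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  n <- length(dates)
  rep_n <- function(x) if (length(x) == n) x else rep_len(x, n)
  tibble::tibble(date = dates, T = rep_n(T), H = rep_n(H), Rf = rep_n(Rf),
                 Cc = rep_n(Cc), Sd = rep_n(Sd), Ws = rep_n(Ws),
                 Wd = rep_n(Wd), Wg = rep_n(Wg))
}

# A pollen series over full calendar years from a named list
# year -> concentration vector (recycled/padded with zeros to year length).
pollen_from_daily <- function(daily_by_year) {
  rows <- lapply(names(daily_by_year), function(y) {
    dates <- seq(as.Date(paste0(y, "-01-01")), as.Date(paste0(y, "-12-31")),
                 by = "day")
    conc <- rep(0, length(dates))
    v <- daily_by_year[[y]]
    conc[seq_along(v)] <- v
    tibble::tibble(date = dates, concentration = conc)
  })
  dplyr::bind_rows(rows)
}

# Cached synthetic datasets (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

noiseless_dataset <- function() {
  if (is.null(.fixture_env$noiseless)) {
    .fixture_env$noiseless <- make_dataset(climate_config(seed = 1),
                                           truth_params(), noise_cv = 0)
  }
  .fixture_env$noiseless
}

noisy_dataset <- function() {
  if (is.null(.fixture_env$noisy)) {
    .fixture_env$noisy <- make_dataset(climate_config(seed = 1),
                                       truth_params())
  }
  .fixture_env$noisy
}

# Independent brute-force calibration oracles: scalar enumeration over a
# small grid using only the public one-candidate primitives, with a
# day-by-day scan for the training predictions.
brute_start_candidates <- function(w, sea, grid, epsilon = 1e-6,
                                   rsd_max = 50) {
  out <- list()
  n <- nrow(sea)
  for (F1 in grid$F1) for (d in grid$d) for (cc in grid$c) {
    p <- start_forcing_params(F1, d, cc)
    units <- vapply(seq_len(n), function(i)
      sigmoid_forcing_sum(w, sea$year[i], p, sea$start_doy_5[i]), 0)
    M <- mean(units); s <- sd(units); rsd <- 100 * s / M
    if (M <= epsilon || rsd > rsd_max) next
    onset_doy <- day_of_year(as.Date(paste0("2005-", F1)))
    preds <- vapply(seq_len(n), function(i) {
      for (t in onset_doy:181) {
        if (sigmoid_forcing_sum(w, sea$year[i], p, t) >= M) return(t)
      }
      NA_integer_
    }, 0L)
    out[[length(out) + 1L]] <-
      tibble::tibble(F1 = F1, d = d, c = cc, M = M, sd = s, rsd = rsd,
                     train_mae = mean(abs(preds - sea$start_doy_5)))
  }
  dplyr::bind_rows(out)
}

brute_peak_candidates <- function(w, sea, grid, epsilon = 1e-6,
                                  rsd_max = 50) {
  out <- list()
  n <- nrow(sea)
  for (TD in grid$T_D) for (Th in grid$Th) {
    p <- peak_heat_params(TD, Th)
    units <- vapply(seq_len(n), function(i)
      heat_sum(w, sea$year[i], p, sea$start_doy_5[i], sea$peak_doy[i]), 0)
    M <- mean(units); s <- sd(units); rsd <- 100 * s / M
    if (M <= epsilon || rsd > rsd_max) next
    preds <- vapply(seq_len(n), function(i) {
      for (t in (sea$start_doy_5[i] + 1):181) {
        if (heat_sum(w, sea$year[i], p, sea$start_doy_5[i], t) >= M)
          return(t)
      }
      NA_integer_
    }, 0L)
    out[[length(out) + 1L]] <-
      tibble::tibble(T_D = TD, Th = Th, M = M, sd = s, rsd = rsd,
                     train_mae = mean(abs(preds - sea$peak_doy)))
  }
  dplyr::bind_rows(out)
}

# Small weather/season toy shared by the oracle-agreement tests.
toy_calibration_case <- function() {
  set.seed(33)
  w <- flat_weather("2003-10-01", "2006-12-31")
  w$T <- 18 - 10 * cos(2 * pi * day_of_year(w$date) / 365) +
    rnorm(nrow(w), 0, 1.5)
  sea <- tibble::tibble(year = 2004:2006, start_doy_2_5 = c(63, 60, 66),
                        start_doy_5 = c(65, 61, 68),
                        peak_doy = c(70, 67, 74))
  list(weather = w, seasons = sea)
}

# Reduced calibration grid that still contains the generator's truth.
reduced_start_grid <- function() {
  list(F1 = pollenseason:::md_seq("01-15", "02-15"),
       d = seq(-2, -0.25, by = 0.25), c = 10:20)
}

reduced_peak_grid <- function() list(T_D = 10:20, Th = 5:15)
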
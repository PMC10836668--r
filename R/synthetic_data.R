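# Synthetic multi-year daily weather and pollen series with known
# ground-truth phenological parameters.
#
# The weather generator emulates a subtropical-highland climate like
# Islamabad's: sinusoidal annual temperature cycle around a 20.3 degC mean
# with AR(1) day-to-day persistence, plus simple bounded stochastic models
# for the seven other variables.  The pollen generator is driven by the
# same forcing equations the calibration searches over - each year's
# ground-truth start day is the first crossing of the sigmoid forcing
# requirement and the peak day the first crossing of the heat-sum
# requirement - so grid calibration on the output is a parameter-recovery
# problem with a known answer, and window-mean temperature is
# mechanistically correlated with the start day for the regression models.

#' Ground-truth phenological parameters for the generator
#'
#' Defaults sit inside the calibration grids (onset 31 January, steepness
#' -0.25, threshold 15 degC; peak trigger 16 degC, base 11 degC) so that a
#' grid search over generated data can recover them.  Requirements are
#' sized so that, under the default climate, the start is typically
#' triggered in early March and the peak a few days later.
#'
#' @param F1 heat-accumulation onset (month-day key).
#' @param d sigmoid steepness (< 0).
#' @param c forcing temperature threshold, degC.
#' @param M_start required start forcing units (dimensionless, > 0).
#' @param T_D peak-accumulation trigger temperature, degC.
#' @param Th peak heat-sum base temperature, degC.
#' @param M_peak required peak heat units, degC day (> 0).
#' @param season_length pollen season length, days.
#' @param peak_magnitude maximum daily concentration, grains/m^3 (the
#'   intense short spring season of paper mulberry reaches ~40,000).
#' @param shape skewness parameter of the seasonal release kernel.
#' @param onset_level release level on the trigger day as a fraction of the
#'   peak: catkin opening is abrupt once the thermal requirement is met, so
#'   release jumps to this plateau immediately and holds it until the
#'   rising limb of the bell overtakes it (keeps the season curve
#'   unimodal).
#' @return list of class `truth_params`.
#' @export
truth_params <- function(F1 = "01-31", d = -1, c = 15, M_start = 12,
                         T_D = 15, Th = 8, M_peak = 25, season_length = 45,
                         peak_magnitude = 40000, shape = 3,
                         onset_level = 0.55) {
  check_monthday(F1)
  stopifnot(d < 0, M_start > 0, M_peak > 0, season_length >= 10,
            peak_magnitude > 0, shape > 0, onset_level >= 0, onset_level < 1)
  structure(list(F1 = F1, d = d, c = c, M_start = M_start, T_D = T_D,
                 Th = Th, M_peak = M_peak, season_length = season_length,
                 peak_magnitude = peak_magnitude, shape = shape,
                 onset_level = onset_level),
            class = "truth_params")
}

#' Climate configuration for the weather generator
#'
#' @param n_years number of generated calendar years (>= 2).
#' @param start_year first calendar year.
#' @param annual_mean_T,annual_amplitude_T mean and semi-amplitude of the
#'   sinusoidal temperature cycle, degC.
#' @param ar1_rho AR(1) day-to-day persistence of temperature noise.
#' @param noise_sd_T innovation SD of the temperature noise, degC.
#' @param year_offset_sd SD of a per-season temperature offset, degC: each
#'   July-June season year is uniformly warmer or colder by one draw,
#'   giving the warm-spring/cold-spring contrast real records show (season
#'   start days in Islamabad spread over roughly three weeks).
#' @param seed RNG seed.
#' @param extra named list tweaking the simple models of the other
#'   variables (means/amplitudes/SDs); see the function body for keys.
#' @return list of class `climate_config`.
#' @export
climate_config <- function(n_years = 15, start_year = 2004,
                           annual_mean_T = 20.3, annual_amplitude_T = 11,
                           ar1_rho = 0.65, noise_sd_T = 2.4,
                           year_offset_sd = 1.2, seed = 1L,
                           extra = list()) {
  stopifnot(n_years >= 2, noise_sd_T >= 0, ar1_rho >= 0, ar1_rho < 1,
            annual_amplitude_T >= 0, year_offset_sd >= 0)
  defaults <- list(
    H_mean = 62, H_amp = 12, H_sd = 9,        # %, moist winters
    Rf_p = 0.30, Rf_mean = 6,                 # wet-day prob, mean mm
    Cc_mean = 45, Cc_amp = 10, Cc_sd = 18,    # %
    Sd_mean = 7.5, Sd_amp = 3, Sd_sd = 1.6,   # hours
    Ws_mean = 8, Ws_sd = 2.5,                 # km/h
    Wg_factor = 1.8, Wg_sd = 3                # gust ~ factor * speed
  )
  defaults[names(extra)] <- extra
  structure(c(list(n_years = as.integer(n_years),
                   start_year = as.integer(start_year),
                   annual_mean_T = annual_mean_T,
                   annual_amplitude_T = annual_amplitude_T,
                   ar1_rho = ar1_rho, noise_sd_T = noise_sd_T,
                   year_offset_sd = year_offset_sd,
                   seed = as.integer(seed)), defaults),
            class = "climate_config")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate daily weather
#'
#' Daily mean temperature follows
#' `annual_mean_T - annual_amplitude_T * cos(2 pi doy / 365)` plus AR(1)
#' noise; the other variables follow simple bounded seasonal models.  The
#' series runs from 1 October of `start_year - 1` (so phenological onsets
#' in the preceding autumn are always covered) through 31 December of the
#' last year.  Identical seeds give identical output.
#'
#' @param config a [climate_config()].
#' @return weather tibble.
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "climate_config"))
  set.seed(config$seed)
  dates <- seq(as.Date(sprintf("%d-10-01", config$start_year - 1)),
               as.Date(sprintf("%d-12-31",
                               config$start_year + config$n_years - 1)),
               by = "day")
  n <- length(dates)
  doy <- day_of_year(dates)
  phase <- cos(2 * pi * doy / 365)
  eps <- rnorm(n, 0, config$noise_sd_T)
  ar <- numeric(n)
  if (n > 0) ar[1] <- eps[1]
  for (i in seq_len(n - 1L)) ar[i + 1L] <- config$ar1_rho * ar[i] + eps[i + 1L]
  # season-year offset: one draw per July-June year, so a whole winter and
  # the following spring are jointly warm or cold
  season_year <- as.integer(format(dates, "%Y")) +
    as.integer(format(dates, "%m") >= "07")
  sy <- sort(unique(season_year))
  offsets <- setNames(rnorm(length(sy), 0, config$year_offset_sd), sy)
  tavg <- config$annual_mean_T - config$annual_amplitude_T * phase + ar +
    unname(offsets[as.character(season_year)])
  wet <- runif(n) < config$Rf_p
  ws <- clip(rnorm(n, config$Ws_mean, config$Ws_sd), 0, Inf)
  tibble(
    date = dates,
    T = tavg,
    H = clip(config$H_mean + config$H_amp * phase + rnorm(n, 0, config$H_sd),
             0, 100),
    Rf = ifelse(wet, -config$Rf_mean * log(runif(n)), 0),  # exponential
    Cc = clip(config$Cc_mean + config$Cc_amp * phase +
                rnorm(n, 0, config$Cc_sd), 0, 100),
    Sd = clip(config$Sd_mean - config$Sd_amp * phase +
                rnorm(n, 0, config$Sd_sd), 0, 24),
    Ws = ws,
    Wd = runif(n, 0, 360) %% 360,
    Wg = clip(config$Wg_factor * ws + rnorm(n, 0, config$Wg_sd), 0, Inf)
  )
}

# ground-truth season timing for one year implied by the forcing equations
truth_season <- function(weather, truth, year) {
  start_params <- start_forcing_params(truth$F1, truth$d, truth$c)
  start <- tryCatch(
    predict_day_phenology(start_params, weather, year, M = truth$M_start),
    error = function(e) stop("year ", year, ": ", conditionMessage(e),
                             call. = FALSE))
  peak <- tryCatch(
    predict_day_phenology(peak_heat_params(truth$T_D, truth$Th), weather,
                          year, start_day = start, M = truth$M_peak),
    error = function(e) stop("year ", year, ": ", conditionMessage(e),
                             call. = FALSE))
  c(start = start, peak = peak)
}

#' Simulate daily pollen concentrations
#'
#' For each calendar year fully covered by the weather series (including
#' the preceding 1 October), the ground-truth start day is the first day
#' the sigmoid forcing sum reaches `M_start` and the peak day the first
#' day the post-start heat sum reaches `M_peak`.  Concentrations form a
#' skewed unimodal bell `(u/m)^shape * exp(shape * (1 - u/m))` over
#' `season_length` days from the start (u is the day within the season, m
#' the peak position), scaled to `peak_magnitude`, multiplied by lognormal
#' noise with coefficient of variation `noise_cv`, and zero outside the
#' season.  An optional small late-summer bump (off by default) mimics the
#' secondary flowering period.
#'
#' @param weather weather tibble.
#' @param truth a [truth_params()].
#' @param noise_cv coefficient of variation of multiplicative noise.
#' @param seed RNG seed.
#' @param years years to generate; defaults to all coverable years.
#' @param summer_bump magnitude of the optional late-summer bump
#'   (grains/m^3, 0 disables it).
#' @return list with `pollen` (tibble) and `truth_seasons` (tibble
#'   `year, start_doy, peak_doy` of the constructed ground truth).
#' @export
simulate_pollen <- function(weather, truth, noise_cv = 0.15, seed = 1L,
                            years = NULL, summer_bump = 0) {
  stopifnot(inherits(truth, "truth_params"), noise_cv >= 0)
  if (is.null(years)) {
    all_years <- unique(as.integer(format(weather$date, "%Y")))
    years <- Filter(function(y) {
      min(weather$date) <= as.Date(sprintf("%d-10-01", y - 1)) &&
        max(weather$date) >= as.Date(sprintf("%d-12-31", y))
    }, all_years)
  }
  if (!length(years)) {
    stop("weather series covers no full pollen year (1 Oct .. 31 Dec)",
         call. = FALSE)
  }
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- lapply(years, function(y) {
    ts <- truth_season(weather, truth, y)
    dates <- seq(as.Date(sprintf("%d-01-01", y)),
                 as.Date(sprintf("%d-12-31", y)), by = "day")
    conc <- numeric(length(dates))
    u <- seq_len(truth$season_length)
    m <- ts["peak"] - ts["start"] + 1
    v <- u / m
    kernel <- v^truth$shape * exp(truth$shape * (1 - v))
    # abrupt onset: plateau at onset_level * peak until the bell overtakes
    kernel[u <= m] <- pmax(kernel[u <= m], truth$onset_level)
    idx <- ts["start"] + u - 1L
    ok <- idx >= 1 & idx <= length(dates)
    conc[idx[ok]] <- truth$peak_magnitude * kernel[ok]
    if (summer_bump > 0) {
      doy <- seq_along(dates)
      conc <- conc + summer_bump * exp(-0.5 * ((doy - 210) / 12)^2)
    }
    if (noise_cv > 0) {
      noisy <- conc > 0
      conc[noisy] <- conc[noisy] *
        exp(rnorm(sum(noisy), -sdlog^2 / 2, sdlog))
    }
    list(pollen = tibble(date = dates, concentration = pmax(conc, 0)),
         season = tibble(year = y, start_doy = unname(ts["start"]),
                         peak_doy = unname(ts["peak"])))
  })
  list(pollen = bind_rows(lapply(rows, `[[`, "pollen")),
       truth_seasons = bind_rows(lapply(rows, `[[`, "season")))
}

#' Generate a complete synthetic dataset
#'
#' Bundles [simulate_weather()] and [simulate_pollen()] (the pollen seed is
#' derived from the climate seed) and returns the constructed ground-truth
#' season days for use as test oracles.
#'
#' @param config a [climate_config()].
#' @param truth a [truth_params()].
#' @param noise_cv concentration noise, see [simulate_pollen()].
#' @param summer_bump see [simulate_pollen()].
#' @return list with `weather`, `pollen`, `truth_seasons` and `years`.
#' @export
make_dataset <- function(config = climate_config(), truth = truth_params(),
                         noise_cv = 0.15, summer_bump = 0) {
  weather <- simulate_weather(config)
  years <- seq(config$start_year, config$start_year + config$n_years - 1L)
  sim <- simulate_pollen(weather, truth, noise_cv = noise_cv,
                         seed = config$seed + 1L, years = years,
                         summer_bump = summer_bump)
  list(weather = weather, pollen = sim$pollen,
       truth_seasons = sim$truth_seasons, years = years)
}
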
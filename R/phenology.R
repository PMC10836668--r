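# Thermal-forcing phenological models.
#
# Start day: daily sigmoid forcing 1 / (1 + exp(d * (T - c))) accumulated
# from a calendar onset F1; flowering (season start) is triggered when the
# running sum reaches the species-specific requirement M.  d < 0 makes the
# contribution rise with temperature towards 1; c is the temperature at
# which a day contributes 0.5 units, so the sigmoid itself realises the
# "only above the threshold does heat count" behaviour and no hard cutoff
# is applied.
#
# Peak day: growing-degree heat max(T - Th, 0) accumulated from the first
# day after the season start whose mean temperature reaches the trigger
# T_D; the peak is triggered when the heat sum reaches its requirement M
# (degC day).  Contributions are clamped at zero so cold days cannot erase
# accumulated heat.
#
# All parameters are unknown for paper mulberry and are calibrated by
# brute force over the full grid, keeping combinations with non-zero mean
# per-year units and relative SD <= 50%, then choosing by training MAE.

#' Forcing/heat parameter constructors
#'
#' `start_forcing_params()` holds the sigmoid start-model parameters
#' (onset month-day `F1`, steepness `d < 0`, threshold `c` in degC);
#' `peak_heat_params()` holds the peak heat-sum parameters (trigger `T_D`,
#' base `Th`, both degC).
#'
#' @param F1 accumulation onset as month-day key (1 Oct-28 Feb grid).
#' @param d sigmoid steepness, dimensionless, strictly negative.
#' @param c temperature threshold, degC.
#' @param T_D trigger temperature, degC.
#' @param Th heat-sum base temperature, degC.
#' @return parameter list of class `start_forcing_params` /
#'   `peak_heat_params`.
#' @export
start_forcing_params <- function(F1, d, c) {
  check_monthday(F1)
  stopifnot(is.numeric(d), length(d) == 1, d < 0,
            is.numeric(c), length(c) == 1, c >= 0, c <= 40)
  structure(list(F1 = F1, d = d, c = c), class = "start_forcing_params")
}

#' @rdname start_forcing_params
#' @export
peak_heat_params <- function(T_D, Th) {
  stopifnot(T_D >= 0, T_D <= 40, Th >= 0, Th <= 40)
  structure(list(T_D = T_D, Th = Th), class = "peak_heat_params")
}

# Date of onset F1 for a given season year: October-December onsets fall
# in the preceding calendar year.
onset_date <- function(year, F1) {
  if (md_num(F1) >= md_num("10-01")) md_date(year - 1, F1)
  else md_date(year, F1)
}

# Temperature series (optionally blended after the issue date) over
# [from_date, to_date] of one season year.
temperature_series <- function(weather, year, from_date, to_date,
                               blend = NULL, training_years = NULL) {
  dates <- seq(from_date, to_date, by = "day")
  idx <- match(dates, weather$date)
  if (anyNA(idx)) {
    stop("weather data do not cover ", dates[which(is.na(idx))[1]],
         call. = FALSE)
  }
  tavg <- weather$T[idx]
  if (!is.null(blend) && blend$w_obs < 1) {
    post <- dates > md_date(year, blend$issue_date) & monthday(dates) != "02-29"
    if (any(post)) {
      if (is.null(training_years)) {
        stop("training_years required for post-issue blending", call. = FALSE)
      }
      mds <- monthday(dates[post])
      hist <- historical_monthday_matrix(weather, unique(mds), training_years)
      tavg[post] <- blend$w_obs * tavg[post] +
        blend$w_hist * hist[match(mds, rownames(hist)), "T"]
    }
  }
  list(dates = dates, tavg = tavg)
}

#' Sigmoid forcing sum for the season start model
#'
#' Sum over days from the onset `F1` through `until_doy` (inclusive) of
#' `1 / (1 + exp(d * (tavg - c)))`.  Each daily term lies in (0, 1); the
#' sum runs across the year boundary when `F1` falls in October-December.
#'
#' @param weather weather tibble.
#' @param year season (calendar) year.
#' @param params a [start_forcing_params()].
#' @param until_doy last accumulated day, as day-of-year of `year`.
#' @return forcing units (dimensionless).
#' @export
sigmoid_forcing_sum <- function(weather, year, params, until_doy) {
  stopifnot(inherits(params, "start_forcing_params"))
  ts <- temperature_series(weather, year, onset_date(year, params$F1),
                           doy_date(year, until_doy))
  sum(1 / (1 + exp(params$d * (ts$tavg - params$c))))
}

#' Clamped heat sum for the season peak model
#'
#' Accumulates `max(Tavg - Th, 0)` from the trigger day `D_T` (the first
#' day strictly after `start_doy` with `Tavg >= T_D`) through `until_doy`
#' inclusive; returns 0 when the trigger has not occurred by `until_doy`.
#'
#' @param weather weather tibble.
#' @param year season year.
#' @param params a [peak_heat_params()].
#' @param start_doy season start day-of-year (accumulation origin).
#' @param until_doy last accumulated day-of-year; `>= start_doy`.
#' @return heat units (degC day).
#' @export
heat_sum <- function(weather, year, params, start_doy, until_doy) {
  stopifnot(inherits(params, "peak_heat_params"), until_doy >= start_doy)
  if (until_doy == start_doy) return(0)
  ts <- temperature_series(weather, year, doy_date(year, start_doy + 1),
                           doy_date(year, until_doy))
  trig <- which(ts$tavg >= params$T_D)[1]
  if (is.na(trig)) return(0)
  sum(pmax(ts$tavg[trig:length(ts$tavg)] - params$Th, 0))
}

#' Default calibration grids
#'
#' Start model: onsets `F1` from 1 October to 28 February (151 dates),
#' steepness `d` from -10 to -0.25 in steps of 0.25 (40 values, zero
#' excluded since `d` is strictly negative), threshold `c` from 0 to 40 degC
#' in 1 degC steps (41 values) - 247,640 combinations.  Peak model: trigger
#' `T_D` and base `Th` each 0-40 degC in 1 degC steps (1,681 combinations).
#'
#' @param mode `"start"` or `"peak"`.
#' @return named list of grid axes.
#' @export
phenology_grid <- function(mode = c("start", "peak")) {
  mode <- match.arg(mode)
  if (mode == "start") {
    list(F1 = md_seq("10-01", "02-28"), d = seq(-10, -0.25, by = 0.25),
         c = seq(0, 40, by = 1))
  } else {
    list(T_D = seq(0, 40, by = 1), Th = seq(0, 40, by = 1))
  }
}

# first index t with cum[t] >= target, for a non-decreasing cum vector;
# NA when never reached
first_crossing <- function(cum, target) {
  pos <- findInterval(target, cum, left.open = TRUE) + 1L
  ifelse(pos > length(cum), NA_integer_, pos)
}

#' Brute-force candidate grid with consistency filters
#'
#' For every parameter combination, accumulates per-training-year forcing
#' units to each year's observed season start day (start mode, sigmoid
#' forcing from `F1`) or from the observed start day to the observed peak
#' day (peak mode, clamped heat sum), and computes their mean `M`, standard
#' deviation and relative SD.  Combinations with `M <= epsilon` (forcing
#' must be non-zero to start pollination) or `RSD > rsd_max` (inconsistent
#' across years) are discarded; survivors carry the training MAE of
#' predicting each year's date by the first crossing of `M`.
#'
#' Internally vectorised over the grid; results are identical to scanning
#' combinations one at a time with [sigmoid_forcing_sum()]/[heat_sum()].
#'
#' @param weather weather tibble.
#' @param seasons season dates table.
#' @param mode `"start"` or `"peak"`.
#' @param criterion `"5"` or `"2.5"`.
#' @param training_years years used for calibration (>= 3).
#' @param grid grid axes, see [phenology_grid()].
#' @param epsilon non-zero threshold for `M`, default `1e-6`.
#' @param rsd_max relative-SD filter in percent, default 50.
#' @param compute_mae attach `train_mae` (default TRUE).
#' @param include_start_day accumulate start-model units through the
#'   observed start day (default); `FALSE` stops on the day before.
#' @return tibble of surviving candidates in grid order: parameter columns,
#'   `M`, `sd`, `rsd`, `train_mae`, plus per-year unit columns `units.<year>`.
#' @export
candidate_grid <- function(weather, seasons, mode = c("start", "peak"),
                           criterion = "5", training_years = NULL,
                           grid = NULL, epsilon = 1e-6, rsd_max = 50,
                           compute_mae = TRUE, include_start_day = TRUE) {
  mode <- match.arg(mode)
  if (is.null(grid)) grid <- phenology_grid(mode)
  if (is.null(training_years)) training_years <- seasons$year
  train <- seasons[seasons$year %in% training_years, , drop = FALSE]
  train <- train[order(train$year), , drop = FALSE]
  if (nrow(train) < 3) stop("need at least 3 training years", call. = FALSE)
  if (mode == "start") {
    grid_start_candidates(weather, train, criterion, grid, epsilon, rsd_max,
                          compute_mae, include_start_day)
  } else {
    grid_peak_candidates(weather, train, criterion, grid, epsilon, rsd_max,
                         compute_mae)
  }
}

grid_start_candidates <- function(weather, train, criterion, grid, epsilon,
                                  rsd_max, compute_mae,
                                  include_start_day = TRUE) {
  stopifnot(all(c("F1", "d", "c") %in% names(grid)))
  years <- train$year
  obs <- train[[start_column(criterion)]]
  nF <- length(grid$F1); pairs <- expand_grid(d = grid$d, c = grid$c)
  np <- nrow(pairs)
  # per year: daily sigmoid terms for every (d, c) pair over the full
  # season span (1 Oct preceding year .. 30 Jun), cumulative in time
  per_year <- lapply(seq_along(years), function(i) {
    yr <- years[i]
    ts <- temperature_series(weather, yr, as.Date(sprintf("%d-10-01", yr - 1)),
                             as.Date(sprintf("%d-06-30", yr)))
    z <- outer(ts$tavg, pairs$c, "-")            # L x np: tavg - c
    z <- sweep(z, 2, pairs$d, "*")
    S <- apply(1 / (1 + exp(z)), 2, cumsum)      # L x np running forcing
    onset <- as.Date(ifelse(md_num(grid$F1) >= 1001L,
                            paste0(yr - 1, "-", grid$F1),
                            paste0(yr, "-", grid$F1)))
    pos <- match(onset, ts$dates)
    if (anyNA(pos)) stop("onset date missing from weather span")
    end_pos <- match(doy_date(yr, obs[i]), ts$dates)
    if (!include_start_day) end_pos <- end_pos - 1L
    list(dates = ts$dates, S = S, onset_pos = pos, end_pos = end_pos)
  })
  # units matrix: rows = candidates in (F1, d, c) grid order, cols = years;
  # column i of D below holds all (d, c) pairs for onset i, so flattening
  # column-major matches expand_grid(F1, d, c) with c varying fastest
  units <- sapply(per_year, function(py) {
    S0 <- rbind(0, py$S)[py$onset_pos, , drop = FALSE]      # nF x np
    D <- matrix(py$S[py$end_pos, ], np, nF) - t(S0)
    as.vector(D)
  })
  cand <- expand_grid(F1 = grid$F1, d = grid$d, c = grid$c)
  out <- finish_candidates(cand, units, years, epsilon, rsd_max)
  if (compute_mae && nrow(out)) {
    pair_of <- (match(out$d, grid$d) - 1L) * length(grid$c) +
      match(out$c, grid$c)
    onset_of <- match(out$F1, grid$F1)
    err <- matrix(NA_real_, nrow(out), length(years))
    for (i in seq_along(years)) {
      py <- per_year[[i]]
      jan1 <- as.Date(sprintf("%d-01-01", years[i]))
      for (k in unique(pair_of)) {
        rows <- which(pair_of == k)
        S <- py$S[, k]
        base <- c(0, S)[py$onset_pos[onset_of[rows]]]
        pos <- first_crossing(S, out$M[rows] + base)
        pred <- as.integer(py$dates[pos] - jan1) + 1L
        err[rows, i] <- abs(pred - obs[i])
      }
    }
    out$train_mae <- rowMeans(err)
    out$train_mae[!is.finite(out$train_mae)] <- Inf
  }
  out
}

grid_peak_candidates <- function(weather, train, criterion, grid, epsilon,
                                 rsd_max, compute_mae) {
  stopifnot(all(c("T_D", "Th") %in% names(grid)))
  years <- train$year
  s_obs <- train[[start_column(criterion)]]
  p_obs <- train$peak_doy
  nTD <- length(grid$T_D); nTh <- length(grid$Th)
  per_year <- lapply(seq_along(years), function(i) {
    yr <- years[i]
    ts <- temperature_series(weather, yr, doy_date(yr, s_obs[i] + 1),
                             as.Date(sprintf("%d-06-30", yr)))
    G <- sapply(grid$Th, function(th) cumsum(pmax(ts$tavg - th, 0)))  # L x nTh
    trig <- vapply(grid$T_D, function(td) {
      w <- which(ts$tavg >= td)[1]
      if (is.na(w)) NA_integer_ else as.integer(w)
    }, integer(1))
    list(tavg = ts$tavg, G = G, trig = trig,
         end_pos = p_obs[i] - s_obs[i])          # position of peak in series
  })
  units <- sapply(per_year, function(py) {
    u <- matrix(0, nTD, nTh)
    e <- py$end_pos
    if (e >= 1) {
      for (a in seq_len(nTD)) {
        tr <- py$trig[a]
        if (!is.na(tr) && tr <= e) {
          base <- if (tr > 1) py$G[tr - 1, ] else 0
          u[a, ] <- py$G[e, ] - base
        }
      }
    }
    as.vector(t(u))  # (T_D, Th) grid order, Th fastest
  })
  cand <- expand_grid(T_D = grid$T_D, Th = grid$Th)
  out <- finish_candidates(cand, units, years, epsilon, rsd_max)
  if (compute_mae && nrow(out)) {
    a_of <- match(out$T_D, grid$T_D)
    b_of <- match(out$Th, grid$Th)
    err <- matrix(NA_real_, nrow(out), length(years))
    for (i in seq_along(years)) {
      py <- per_year[[i]]
      for (b in unique(b_of)) {
        rows <- which(b_of == b)
        G <- py$G[, b]
        tr <- py$trig[a_of[rows]]
        base <- ifelse(is.na(tr), NA_real_, c(0, G)[tr])
        pos <- first_crossing(G, out$M[rows] + base)
        pred <- s_obs[i] + pos  # series starts the day after the start day
        err[rows, i] <- abs(pred - p_obs[i])
      }
    }
    out$train_mae <- rowMeans(err)
    out$train_mae[!is.finite(out$train_mae)] <- Inf
  }
  out
}

# attach M/sd/rsd and apply the non-zero and RSD filters
finish_candidates <- function(cand, units, years, epsilon, rsd_max) {
  if (!is.matrix(units)) units <- matrix(units, nrow = 1)
  M <- rowMeans(units)
  sdv <- sqrt(rowSums((units - M)^2) / (ncol(units) - 1))
  rsd <- ifelse(M > 0, 100 * sdv / M, Inf)
  keep <- M > epsilon & rsd <= rsd_max
  out <- cand[keep, , drop = FALSE]
  out$M <- M[keep]
  out$sd <- sdv[keep]
  out$rsd <- rsd[keep]
  u <- units[keep, , drop = FALSE]
  colnames(u) <- paste0("units.", years)
  bind_cols(out, as_tibble(u))
}

#' Select the calibrated parameter combination
#'
#' Minimum training MAE among the filtered candidates; ties are broken by
#' the smaller relative SD, then by grid order (`F1`, `d`, `c` for the
#' start model; `T_D`, `Th` for the peak model).
#'
#' @param candidates tibble from [candidate_grid()].
#' @return single-row tibble.
#' @export
select_params <- function(candidates) {
  if (!nrow(candidates)) {
    stop("no candidate survived the filters", call. = FALSE)
  }
  if (!"train_mae" %in% names(candidates)) {
    stop("candidates carry no train_mae; rerun with compute_mae = TRUE",
         call. = FALSE)
  }
  candidates[order(candidates$train_mae, candidates$rsd)[1], , drop = FALSE]
}

#' Calibrate a phenological model
#'
#' Runs [candidate_grid()] and [select_params()] and packages the result.
#'
#' @inheritParams candidate_grid
#' @return list of class `pollen_phenology`: `mode`, `criterion`, `params`,
#'   `M`, `sd`, `rsd`, `train_mae`, `n_candidates` (survivor count),
#'   `grid_size`, `training_years`.
#' @export
calibrate_phenology <- function(weather, seasons, mode = c("start", "peak"),
                                criterion = "5", training_years = NULL,
                                grid = NULL, epsilon = 1e-6, rsd_max = 50) {
  mode <- match.arg(mode)
  if (is.null(grid)) grid <- phenology_grid(mode)
  cands <- candidate_grid(weather, seasons, mode, criterion, training_years,
                          grid, epsilon, rsd_max)
  best <- select_params(cands)
  params <- if (mode == "start") {
    start_forcing_params(best$F1, best$d, best$c)
  } else peak_heat_params(best$T_D, best$Th)
  structure(list(
    mode = mode, criterion = as.character(criterion), params = params,
    M = best$M, sd = best$sd, rsd = best$rsd, train_mae = best$train_mae,
    n_candidates = nrow(cands), grid_size = prod(lengths(grid)),
    training_years = if (is.null(training_years)) seasons$year
                     else training_years
  ), class = "pollen_phenology")
}

#' @export
print.pollen_phenology <- function(x, ...) {
  p <- x$params
  cat("<pollen_phenology> ", x$mode, " day model, ", x$criterion,
      "% criterion\n", sep = "")
  if (x$mode == "start") {
    cat("  F1 = ", p$F1, ", d = ", p$d, ", c = ", p$c, " degC\n", sep = "")
  } else {
    cat("  T_D = ", p$T_D, " degC, Th = ", p$Th, " degC\n", sep = "")
  }
  cat("  M = ", round(x$M, 2), " (RSD ", round(x$rsd, 1), "%), train MAE ",
      round(x$train_mae, 2), " days, ", x$n_candidates,
      " surviving candidates\n", sep = "")
  invisible(x)
}

#' Predict a season date from a calibrated phenological model
#'
#' First day-of-year at which the running accumulation (sigmoid forcing
#' from `F1` for start models; clamped heat from the post-start trigger day
#' for peak models) reaches the calibrated requirement `M`, scanning to 30
#' June.  With a [blend_config()], temperatures after the issue date are
#' blended with the training-years climatology.
#'
#' @param model a `pollen_phenology`, or a bare parameter object combined
#'   with `M`.
#' @param weather weather tibble.
#' @param year year to predict.
#' @param blend optional [blend_config()].
#' @param training_years climatology years for blending.
#' @param start_day start day-of-year, required by peak models (observed in
#'   training, predicted at prediction time).
#' @param M accumulation requirement; defaults to `model$M`.
#' @return predicted day-of-year (integer; can be <= 0 if the crossing
#'   happens before 1 January).
#' @export
predict_day_phenology <- function(model, weather, year, blend = NULL,
                                  training_years = NULL, start_day = NULL,
                                  M = NULL) {
  if (inherits(model, "pollen_phenology")) {
    params <- model$params
    if (is.null(M)) M <- model$M
  } else {
    params <- model
    if (is.null(M)) stop("M required when passing bare parameters",
                         call. = FALSE)
  }
  jun30 <- as.Date(sprintf("%d-06-30", year))
  jan1 <- as.Date(sprintf("%d-01-01", year))
  if (inherits(params, "start_forcing_params")) {
    ts <- temperature_series(weather, year, onset_date(year, params$F1),
                             jun30, blend, training_years)
    cum <- cumsum(1 / (1 + exp(params$d * (ts$tavg - params$c))))
    pos <- first_crossing(cum, M)
    if (is.na(pos)) {
      stop("no crossing: forcing never reaches M = ", signif(M, 6),
           " by 30 Jun ", year, call. = FALSE)
    }
    as.integer(ts$dates[pos] - jan1) + 1L
  } else if (inherits(params, "peak_heat_params")) {
    if (is.null(start_day)) stop("peak model needs start_day", call. = FALSE)
    ts <- temperature_series(weather, year, doy_date(year, start_day + 1),
                             jun30, blend, training_years)
    trig <- which(ts$tavg >= params$T_D)[1]
    if (is.na(trig)) {
      stop("no crossing: trigger temperature T_D never reached by 30 Jun ",
           year, call. = FALSE)
    }
    cum <- cumsum(pmax(ts$tavg[trig:length(ts$tavg)] - params$Th, 0))
    pos <- first_crossing(cum, M)
    if (is.na(pos)) {
      stop("no crossing: heat never reaches M = ", signif(M, 6),
           " by 30 Jun ", year, call. = FALSE)
    }
    start_day + (trig - 1L) + pos
  } else {
    stop("unknown parameter object", call. = FALSE)
  }
}
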
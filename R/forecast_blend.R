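# Candidate weather-averaging windows and the observed/climatology blending
# hindcast.
#
# Predictions are issued before the season (default 25 February), so weather
# on later calendar days is not yet known at issue time.  The hindcast
# stand-in for a short-term forecast blends the day's eventual observation
# with its training-years climatology: 0.8 * observed + 0.2 * historical
# mean.  This is an evaluation device, not an operational forecast.

#' Blending configuration
#'
#' @param issue_date month-day key of the prediction issue date
#'   (default `"02-25"`); days up to and including it use pure observations.
#' @param w_obs weight on the observed value for post-issue days.
#' @param w_hist weight on the historical mean; must satisfy
#'   `w_obs + w_hist = 1`.
#' @return list of class `blend_config`.
#' @export
blend_config <- function(issue_date = "02-25", w_obs = 0.8,
                         w_hist = 1 - w_obs) {
  check_monthday(issue_date)
  stopifnot(w_obs >= 0, w_obs <= 1, w_hist >= 0, w_hist <= 1)
  if (abs(w_obs + w_hist - 1) > 1e-12) {
    stop("w_obs + w_hist must equal 1", call. = FALSE)
  }
  structure(list(issue_date = issue_date, w_obs = w_obs, w_hist = w_hist),
            class = "blend_config")
}

#' Enumerate candidate averaging windows
#'
#' Cartesian product of window start dates and end dates (month-day keys,
#' both inclusive, fixed across years).  Defaults span the full search
#' space for the season-start models: starts 1 January-25 February, ends
#' 1 March-11 March, i.e. 56 x 11 = 616 windows.  For the peak-day models
#' pass `end_range = "mps-start"`: the end date is then resolved per year
#' to that year's observed season start day, yielding one window per start
#' date.
#'
#' @param start_range length-2 character vector of month-day keys.
#' @param end_range length-2 character vector, or the sentinel
#'   `"mps-start"`.
#' @return tibble `start_md, end_md` (`end_md` is `NA` under the sentinel).
#' @export
enumerate_windows <- function(start_range = c("01-01", "02-25"),
                              end_range = c("03-01", "03-11")) {
  starts <- md_seq(start_range[1], start_range[2])
  if (identical(end_range, "mps-start")) {
    return(tibble(start_md = starts, end_md = NA_character_))
  }
  ends <- md_seq(end_range[1], end_range[2])
  if (!length(starts) || !length(ends)) stop("empty window range",
                                             call. = FALSE)
  if (max(md_num(starts)) >= min(md_num(ends))) {
    stop("window start range must lie strictly before the end range",
         call. = FALSE)
  }
  expand_grid(start_md = starts, end_md = ends)
}

#' Blended weather value for one calendar day
#'
#' Observed value on or before the issue date; afterwards the convex
#' combination `w_obs * observed + w_hist * historical mean` over the
#' training years.
#'
#' @param weather weather tibble.
#' @param year calendar year of the day being valued.
#' @param md month-day key of the day.
#' @param variable one of `T,H,Rf,Cc,Sd,Ws,Wd,Wg`.
#' @param blend a [blend_config()]; `NULL` means pure observation.
#' @param training_years years used for the historical mean.
#' @return value in the variable's units.
#' @export
blended_value <- function(weather, year, md, variable, blend = blend_config(),
                          training_years = NULL) {
  obs_idx <- match(md_date(year, md), weather$date)
  if (is.na(obs_idx)) {
    stop("no weather observation on ", year, "-", md, call. = FALSE)
  }
  obs <- weather[[variable]][obs_idx]
  if (is.null(blend) || md_num(md) <= md_num(blend$issue_date)) return(obs)
  if (is.null(training_years)) {
    stop("training_years required for post-issue blending", call. = FALSE)
  }
  hist <- historical_mean_by_monthday(weather, md, variable, training_years)
  blend$w_obs * obs + blend$w_hist * hist
}

# Daily (possibly blended) values for all eight variables over a span of
# dates within one season year.  Internal fast path: returns a
# length(dates) x 8 matrix with columns WEATHER_COLS.  Blending applies to
# dates strictly after the issue date resolved in `year` (dates in the
# preceding autumn are past observations and never blended).
blended_daily_matrix <- function(weather, year, dates, blend = NULL,
                                 training_years = NULL) {
  idx <- match(dates, weather$date)
  if (anyNA(idx)) {
    stop("weather data do not cover ", dates[which(is.na(idx))[1]],
         call. = FALSE)
  }
  obs <- sapply(WEATHER_COLS, function(v) weather[[v]][idx])
  if (!is.matrix(obs)) obs <- matrix(obs, nrow = 1,
                                     dimnames = list(NULL, WEATHER_COLS))
  if (is.null(blend) || blend$w_obs == 1) return(obs)
  post <- dates > md_date(year, blend$issue_date)
  if (!any(post)) return(obs)
  if (is.null(training_years)) {
    stop("training_years required for post-issue blending", call. = FALSE)
  }
  mds <- monthday(dates[post])
  keep <- mds != "02-29"  # no climatology for leap day; leave it observed
  if (any(keep)) {
    rows <- which(post)[keep]
    hist <- historical_monthday_matrix(weather, unique(mds[keep]),
                                       training_years)
    h <- hist[match(mds[keep], rownames(hist)), , drop = FALSE]
    obs[rows, ] <- blend$w_obs * obs[rows, , drop = FALSE] + blend$w_hist * h
  }
  obs
}

#' Window mean feature vector
#'
#' Per-variable arithmetic mean of daily (possibly blended) weather values
#' over an inclusive window of one year, the realized regressors of the
#' linear season models.  29 February is excluded so window lengths are
#' comparable across years.
#'
#' @param weather weather tibble.
#' @param year calendar year.
#' @param start_md,end_md inclusive window bounds as month-day keys;
#'   alternatively `end_doy` gives a per-year end as day-of-year (used when
#'   the window ends at that year's season start).
#' @param blend optional [blend_config()] for post-issue days.
#' @param training_years years for the blending climatology.
#' @param end_doy optional day-of-year overriding `end_md`.
#' @return named numeric vector over `T,H,Rf,Cc,Sd,Ws,Wd,Wg`.
#' @export
window_feature_vector <- function(weather, year, start_md, end_md = NULL,
                                  blend = NULL, training_years = NULL,
                                  end_doy = NULL) {
  start_date <- md_date(year, start_md)
  end_date <- if (!is.null(end_doy)) doy_date(year, end_doy)
              else md_date(year, end_md)
  if (end_date < start_date) stop("window end precedes its start",
                                  call. = FALSE)
  dates <- seq(start_date, end_date, by = "day")
  dates <- dates[monthday(dates) != "02-29"]
  m <- blended_daily_matrix(weather, year, dates, blend, training_years)
  colMeans(m)
}
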
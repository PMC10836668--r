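# Main-pollen-season (MPS) metrics: cumulative-percentage start day, spring
# peak day, and the mean-absolute-error metric used for all model evaluation.

#' Season start day by cumulative-percentage criterion
#'
#' First day of the calendar year on which the running cumulative sum of
#' daily pollen concentrations reaches at least `fraction` of the annual
#' total.  The annual total is the full calendar-year sum, matching the
#' standard main-pollen-season definitions (2.5%-97.5% and 5%-95%).
#'
#' @param pollen pollen tibble (`date`, `concentration`).
#' @param year calendar year; must be fully covered by the series.
#' @param fraction cumulative threshold, conventionally 0.025 or 0.05.
#' @return day-of-year (integer).
#' @export
annual_start_day <- function(pollen, year, fraction = 0.05) {
  stopifnot(length(fraction) == 1, fraction > 0, fraction < 1)
  x <- year_slice(pollen, year)
  total <- sum(x$concentration)
  if (total <= 0) stop("annual pollen total is zero in ", year, call. = FALSE)
  cum <- cumsum(x$concentration)
  doy <- which(cum >= fraction * total)[1]
  as.integer(doy)
}

#' Season peak day
#'
#' Day-of-year of the maximum daily concentration within a search window,
#' by default days 1-181 (January-June): the target is the spring season,
#' and restricting the argmax keeps any secondary late-summer rise from
#' capturing it.  Ties are broken by the earliest day.
#'
#' @param pollen pollen tibble.
#' @param year calendar year; must be fully covered.
#' @param search_window inclusive day-of-year interval, default `c(1, 181)`.
#' @return day-of-year (integer).
#' @export
annual_peak_day <- function(pollen, year, search_window = c(1L, 181L)) {
  stopifnot(length(search_window) == 2, search_window[1] <= search_window[2])
  x <- year_slice(pollen, year)
  doy <- seq_len(nrow(x))
  keep <- doy >= search_window[1] & doy <= search_window[2]
  conc <- x$concentration[keep]
  if (!length(conc) || max(conc) <= 0) {
    stop("no non-zero pollen concentration in the search window of ", year,
         call. = FALSE)
  }
  as.integer(doy[keep][which.max(conc)])
}

# full-calendar-year slice, erroring on partial coverage
year_slice <- function(pollen, year) {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  idx <- match(days, pollen$date)
  if (anyNA(idx)) {
    stop("pollen series does not fully cover year ", year, call. = FALSE)
  }
  pollen[idx, ]
}

#' Season dates table
#'
#' Per-year start days under both cumulative criteria and the spring peak
#' day, for all fully covered calendar years.
#'
#' @param pollen pollen tibble.
#' @param years years to include; default all fully covered years.
#' @param search_window peak-day search window, see [annual_peak_day()].
#' @return tibble `year, start_doy_2_5, start_doy_5, peak_doy`.
#' @export
season_dates <- function(pollen, years = NULL, search_window = c(1L, 181L)) {
  if (is.null(years)) {
    yrs <- sort(unique(as.integer(format(pollen$date, "%Y"))))
    years <- yrs[vapply(yrs, function(y) {
      !inherits(try(year_slice(pollen, y), silent = TRUE), "try-error")
    }, logical(1))]
  }
  tibble(
    year = as.integer(years),
    start_doy_2_5 = vapply(years, annual_start_day, 0L,
                           pollen = pollen, fraction = 0.025),
    start_doy_5 = vapply(years, annual_start_day, 0L,
                         pollen = pollen, fraction = 0.05),
    peak_doy = vapply(years, annual_peak_day, 0L, pollen = pollen,
                      search_window = search_window)
  )
}

#' Mean absolute error between predicted and actual season dates
#'
#' `mean(|PD_i - AD_i|)` over the evaluation years; lower is more accurate.
#'
#' @param predicted,actual equal-length vectors of day-of-year values.
#' @return MAE in days.
#' @export
mean_absolute_error <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  if (!length(predicted)) stop("need at least one evaluation year",
                               call. = FALSE)
  mean(abs(predicted - actual))
}
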
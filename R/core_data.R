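# Domain containers, calendar conventions and CSV ingest for daily weather
# and pollen series.
#
# A weather table has columns date, T, H, Rf, Cc, Sd, Ws, Wd, Wg:
#   T  daily mean temperature, degC       H  relative humidity, %
#   Rf rainfall, mm                       Cc cloud cover, %
#   Sd sunshine duration, hours           Ws wind speed, km/h
#   Wd wind direction, degrees [0, 360)   Wg wind gust, km/h
# A pollen table has columns date, concentration (grains/m^3).
# Units are fixed: regression coefficients are unit-dependent.

# variable -> c(lower bound, upper bound); upper bound is exclusive for Wd
WEATHER_BOUNDS <- list(
  T  = c(-Inf, Inf),
  H  = c(0, 100),
  Rf = c(0, Inf),
  Cc = c(0, 100),
  Sd = c(0, 24),
  Ws = c(0, Inf),
  Wd = c(0, 360),
  Wg = c(0, Inf)
)

#' Day of year
#'
#' 1-based ordinal day within the calendar year (1 January is 1; in leap
#' years 29 February is 60 and later dates shift by one).  Cross-year
#' alignment elsewhere in the package is done by month-day key, not by
#' day-of-year, so leap days never desynchronise multi-year means.
#'
#' @param date a `Date` vector.
#' @return integer vector of ordinal days.
#' @export
#' @examples
#' day_of_year(as.Date("2005-03-08"))  # 67
day_of_year <- function(date) {
  stopifnot(inherits(date, "Date"))
  as.integer(lubridate::yday(date))
}

# Date of a 1-based day-of-year within `year` (continuous: doy may exceed
# the year length or be <= 0, mapping into neighbouring years).
doy_date <- function(year, doy) {
  as.Date(sprintf("%d-01-01", year)) + (doy - 1)
}

# ---- month-day keys --------------------------------------------------------

#' Month-day key of a date
#'
#' @param date a `Date` vector.
#' @return character vector `"MM-DD"`.
#' @export
monthday <- function(date) format(date, "%m-%d")

check_monthday <- function(md) {
  ok <- grepl("^\\d{2}-\\d{2}$", md) &
    !is.na(as.Date(paste0("2000-", md)))  # 2000 is leap: accepts 02-29
  if (!all(ok)) {
    stop("invalid month-day key(s): ", paste(md[!ok], collapse = ", "),
         call. = FALSE)
  }
  invisible(md)
}

# numeric key for ordering month-days within a calendar year
md_num <- function(md) {
  check_monthday(md)
  as.integer(substr(md, 1, 2)) * 100L + as.integer(substr(md, 4, 5))
}

# Date of month-day `md` in calendar year `year`; errors on 02-29 in
# non-leap years.
md_date <- function(year, md) {
  check_monthday(md)
  out <- as.Date(paste0(year, "-", md))
  if (anyNA(out)) {
    stop("month-day ", paste(md[is.na(out)], collapse = ", "),
         " does not exist in year ", year, call. = FALSE)
  }
  out
}

# Inclusive month-day sequence; wraps across the year boundary when
# `from` falls after `to` (e.g. 10-01 .. 02-28).  Reference years are
# non-leap, so 02-29 never appears in a generated sequence.
md_seq <- function(from, to) {
  check_monthday(c(from, to))
  if (md_num(from) <= md_num(to)) {
    d <- seq(md_date(2001, from), md_date(2001, to), by = "day")
  } else {
    d <- seq(md_date(2001, from), md_date(2002, to), by = "day")
  }
  monthday(d)
}

# ---- validation ------------------------------------------------------------

check_contiguous <- function(dates, what) {
  if (anyDuplicated(dates)) {
    stop(what, ": duplicate date(s): ",
         paste(unique(dates[duplicated(dates)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(dates)) dates <- sort(dates)
  full <- seq(min(dates), max(dates), by = "day")
  gap <- setdiff(as.character(full), as.character(dates))
  if (length(gap)) {
    stop(what, ": missing day(s) inside the covered span, first gap at ",
         gap[1], call. = FALSE)
  }
  invisible(TRUE)
}

# Validate (and optionally repair) a weather table against the schema
# invariants.  Missing values are a hard error unless repair_missing = TRUE,
# in which case interior NAs are filled by linear interpolation in time.
validate_weather <- function(weather, repair_missing = FALSE) {
  need <- c("date", WEATHER_COLS)
  if (!identical(names(weather), need)) {
    stop("weather table must have columns ", paste(need, collapse = ","),
         " (got ", paste(names(weather), collapse = ","), ")", call. = FALSE)
  }
  weather <- arrange(weather, .data$date)
  check_contiguous(weather$date, "weather")
  for (v in WEATHER_COLS) {
    x <- weather[[v]]
    if (anyNA(x)) {
      if (!repair_missing) {
        stop("weather: missing value in column ", v, " on ",
             weather$date[which(is.na(x))[1]],
             " (set repair_missing = TRUE to interpolate)", call. = FALSE)
      }
      if (is.na(x[1]) || is.na(x[length(x)])) {
        stop("weather: cannot interpolate missing value at series boundary",
             " in column ", v, call. = FALSE)
      }
      x <- approx(seq_along(x), x, xout = seq_along(x))$y
      weather[[v]] <- x
    }
    b <- WEATHER_BOUNDS[[v]]
    bad <- x < b[1] | x > b[2] | (v == "Wd" & x >= 360)
    if (any(bad)) {
      stop("weather: value out of range in column ", v, " on ",
           weather$date[which(bad)[1]], " (", x[which(bad)[1]], ")",
           call. = FALSE)
    }
  }
  weather
}

validate_pollen <- function(pollen) {
  if (!identical(names(pollen), c("date", "concentration"))) {
    stop("pollen table must have columns date,concentration", call. = FALSE)
  }
  pollen <- arrange(pollen, .data$date)
  check_contiguous(pollen$date, "pollen")
  x <- pollen$concentration
  if (anyNA(x)) {
    stop("pollen: missing concentration on ", pollen$date[which(is.na(x))[1]],
         call. = FALSE)
  }
  if (any(x < 0)) {
    stop("pollen: negative concentration on ", pollen$date[which(x < 0)[1]],
         " (", x[which(x < 0)[1]], ")", call. = FALSE)
  }
  pollen
}

# ---- CSV ingest ------------------------------------------------------------

#' Read a daily weather or pollen CSV
#'
#' Expected schemas (ISO-8601 dates, decimal point):
#' `date,T,H,Rf,Cc,Sd,Ws,Wd,Wg` for weather and `date,concentration` for
#' pollen.  Records are validated against the domain invariants (bounded
#' humidity/cloud cover/sunshine, non-negative rainfall/wind/pollen,
#' unique contiguous daily dates) and returned sorted by date.
#'
#' @param path CSV file path.
#' @param kind `"weather"` or `"pollen"`.
#' @param repair_missing repair interior missing weather values by linear
#'   interpolation instead of erroring (off by default).
#' @return a tibble in the corresponding schema.
#' @export
read_daily_csv <- function(path, kind = c("weather", "pollen"),
                           repair_missing = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  expected <- if (kind == "weather") c("date", WEATHER_COLS) else
    c("date", "concentration")
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(hdr, expected)) {
    stop("schema error in ", path, ": expected header ",
         paste(expected, collapse = ","), ", found ",
         paste(hdr, collapse = ","), call. = FALSE)
  }
  spec <- do.call(readr::cols, c(
    list(date = readr::col_date(format = "%Y-%m-%d")),
    setNames(rep(list(readr::col_double()), length(expected) - 1L),
             expected[-1])
  ))
  df <- readr::read_csv(path, col_types = spec, progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    stop("parse error in ", path, " at row ", prob$row[1], ", column '",
         expected[prob$col[1]], "': expected ", prob$expected[1], ", got '",
         prob$actual[1], "'", call. = FALSE)
  }
  if (anyNA(df$date)) {
    stop("parse error in ", path, ": unparseable date", call. = FALSE)
  }
  if (kind == "weather") validate_weather(df, repair_missing)
  else validate_pollen(df)
}

#' @rdname read_daily_csv
#' @export
read_weather_csv <- function(path, repair_missing = FALSE) {
  read_daily_csv(path, "weather", repair_missing)
}

#' @rdname read_daily_csv
#' @export
read_pollen_csv <- function(path) read_daily_csv(path, "pollen")

#' Write a daily weather or pollen CSV
#'
#' Writes the schema read back by [read_daily_csv()]; read/write round-trips
#' are the identity on valid tables.
#'
#' @param x weather or pollen tibble.
#' @param path output file path.
#' @param kind `"weather"` or `"pollen"`.
#' @export
write_daily_csv <- function(x, path, kind = c("weather", "pollen")) {
  kind <- match.arg(kind)
  x <- if (kind == "weather") validate_weather(x) else validate_pollen(x)
  readr::write_csv(x, path)
  invisible(path)
}

# ---- dataset bundle --------------------------------------------------------

#' Bundle weather and pollen series into a dataset
#'
#' Validates both tables and their pairing.  The weather series may start
#' before the first pollen year (it must: phenological heat accumulation can
#' begin on 1 October of the preceding autumn) but has to cover 1 October
#' preceding each pollen year through that year's end.
#'
#' @param weather weather tibble (see [read_daily_csv()]).
#' @param pollen pollen tibble.
#' @return list with elements `weather`, `pollen` and `years` (calendar years
#'   fully covered by the pollen series), class `pollen_dataset`.
#' @export
pollen_dataset <- function(weather, pollen) {
  weather <- validate_weather(weather)
  pollen <- validate_pollen(pollen)
  yrs <- sort(unique(as.integer(format(pollen$date, "%Y"))))
  full <- vapply(yrs, function(y) {
    all(seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)),
            by = "day") %in% pollen$date)
  }, logical(1))
  yrs <- yrs[full]
  if (!length(yrs)) stop("pollen series covers no complete calendar year",
                         call. = FALSE)
  for (y in yrs) {
    if (min(weather$date) > as.Date(sprintf("%d-10-01", y - 1)) ||
        max(weather$date) < as.Date(sprintf("%d-12-31", y))) {
      stop("weather series must cover 1 Oct ", y - 1, " through 31 Dec ", y,
           " for pollen year ", y, call. = FALSE)
    }
  }
  structure(list(weather = weather, pollen = pollen, years = yrs),
            class = "pollen_dataset")
}

#' @export
print.pollen_dataset <- function(x, ...) {
  cat("<pollen_dataset> ", length(x$years), " pollen year(s) ",
      min(x$years), "-", max(x$years), "; weather ",
      as.character(min(x$weather$date)), " .. ",
      as.character(max(x$weather$date)), "\n", sep = "")
  invisible(x)
}

# ---- cross-year climatology ------------------------------------------------

#' Historical mean of a weather variable on a calendar day
#'
#' Arithmetic mean over the listed years of the variable on a fixed
#' month-day.  29 February is excluded from all cross-year means by policy.
#'
#' @param weather weather tibble.
#' @param md month-day key `"MM-DD"`.
#' @param variable one of `T,H,Rf,Cc,Sd,Ws,Wd,Wg`.
#' @param years calendar years to average over (typically training years).
#' @return mean value in the variable's units.
#' @export
historical_mean_by_monthday <- function(weather, md, variable, years) {
  if (!length(years)) stop("years must be non-empty", call. = FALSE)
  if (identical(md, "02-29")) {
    stop("29 February is excluded from cross-year means by policy",
         call. = FALSE)
  }
  if (!variable %in% WEATHER_COLS) {
    stop("unknown weather variable: ", variable, call. = FALSE)
  }
  dates <- md_date(years, md)  # vectorised over years
  idx <- match(dates, weather$date)
  if (anyNA(idx)) {
    stop("month-day ", md, " absent from weather data in year(s) ",
         paste(years[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  mean(weather[[variable]][idx])
}

# Matrix of historical monthday means: rows = monthdays, cols = WEATHER_COLS.
# Internal fast path used by window searches; 02-29 rows are disallowed.
historical_monthday_matrix <- function(weather, mds, years) {
  if (any(mds == "02-29")) stop("02-29 not allowed in climatology")
  idx <- outer(mds, years, function(m, y) match(as.Date(paste0(y, "-", m)),
                                                weather$date))
  if (anyNA(idx)) stop("climatology day absent from weather data")
  out <- sapply(WEATHER_COLS, function(v) {
    m <- matrix(weather[[v]][idx], nrow = length(mds))
    rowMeans(m)
  })
  if (!is.matrix(out)) out <- matrix(out, nrow = 1,
                                     dimnames = list(NULL, WEATHER_COLS))
  rownames(out) <- mds
  out
}
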
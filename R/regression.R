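# Window-searched stepwise linear regression for season-date prediction.
#
# For every candidate averaging window, forward stepwise selection ranks
# nested models by adjusted R^2; the selected variable set is then passed
# through leave-one-out cross-validation over training years, the final
# coefficients being the arithmetic mean of the per-fold fits and the
# model's MAE the mean out-of-fold absolute error.  Windows whose model
# fails the overall F-test gate (p > 0.05) are discarded and the surviving
# window with the smallest LOOCV MAE wins.

#' Ordinary least squares fit with fit statistics
#'
#' Fits `y = a + sum(b_i x_i)` and reports R-squared, adjusted R-squared
#' and the overall F-test p-value.  A constant response is a defined
#' degenerate case: zero slopes, R-squared 0, p-value 1.
#'
#' @param X numeric matrix of predictors (columns named), one row per year.
#' @param y numeric response (day-of-year).
#' @return list with `a`, `b` (named), `r2`, `adj_r2`, `p_value`, `n`, `p`.
#' @export
fit_linear <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("too few years: need n > p + 1 (n = ", n,
                       ", p = ", p, ")", call. = FALSE)
  fit <- ols_fit(X, y)
  if (var(y) == 0) {
    return(c(fit, list(r2 = 0, adj_r2 = 0, p_value = 1, n = n, p = p)))
  }
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  fstat <- (r2 / p) / ((1 - r2) / (n - p - 1))
  c(fit[c("a", "b")],
    list(r2 = r2, adj_r2 = adj_r2,
         p_value = stats::pf(fstat, p, n - p - 1, lower.tail = FALSE),
         n = n, p = p))
}

# bare OLS without fit statistics; exact fits (n = p + 1) are allowed,
# which leave-one-out folds on small training sets rely on
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("X and y dimensions differ", call. = FALSE)
  if (p < 1) stop("need at least one predictor", call. = FALSE)
  if (n < p + 1) stop("too few observations for ", p, " predictors",
                      call. = FALSE)
  if (var(y) == 0) {
    return(list(a = mean(y), b = setNames(rep(0, p), colnames(X)),
                residuals = rep(0, n)))
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < p + 1) stop("rank-deficient design", call. = FALSE)
  list(a = unname(fit$coefficients[1]),
       b = setNames(fit$coefficients[-1], colnames(X)),
       residuals = as.numeric(fit$residuals))
}

#' Forward stepwise selection by adjusted R-squared
#'
#' Iteration k adds, to the k-1 already selected variables, the single
#' remaining candidate maximising adjusted R-squared; after building the
#' full nested sequence, the step with the overall highest adjusted
#' R-squared is returned.  Exact ties keep the earlier candidate in the
#' supplied order (default `T,H,Cc,Sd,Ws,Wd,Wg,Rf`).  Candidates whose fit
#' fails (e.g. zero variance) are skipped.
#'
#' @param X numeric predictor matrix with named columns.
#' @param y numeric response.
#' @param candidates candidate column names in tie-break order.
#' @param exhaustive search all variable subsets instead of the greedy
#'   forward path (comparison mode; identical on orthogonal designs).
#' @return list with `variables` (selected set), `fit` (its [fit_linear()]
#'   result) and `path` (tibble `step, added, adj_r2`; for the exhaustive
#'   mode, the best subset per size).
#' @export
forward_stepwise <- function(X, y, candidates = colnames(X),
                             exhaustive = FALSE) {
  X <- as.matrix(X)
  if (!length(candidates)) stop("need at least one candidate", call. = FALSE)
  stopifnot(all(candidates %in% colnames(X)))
  if (exhaustive) return(best_subset(X, y, candidates))
  selected <- character(0)
  path <- list()
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    best_v <- NULL
    best <- NULL
    for (v in remaining) {
      f <- tryCatch(fit_linear(X[, c(selected, v), drop = FALSE], y),
                    error = function(e) NULL)
      if (is.null(f)) next
      if (is.null(best) || f$adj_r2 > best$adj_r2) {
        best <- f
        best_v <- v
      }
    }
    if (is.null(best_v)) break
    selected <- c(selected, best_v)
    path[[length(path) + 1L]] <- tibble(step = length(selected),
                                        added = best_v,
                                        adj_r2 = best$adj_r2)
  }
  if (!length(path)) stop("no candidate variable could be fitted",
                          call. = FALSE)
  path <- bind_rows(path)
  k <- which.max(path$adj_r2)  # first maximum on exact ties
  vars <- path$added[seq_len(k)]
  list(variables = vars,
       fit = fit_linear(X[, vars, drop = FALSE], y),
       path = path)
}

# exhaustive best-subset comparison mode: best adjusted R^2 per subset
# size, then the overall maximum; ties keep the earlier enumeration,
# which lists lower-index (tie-order) variables first
best_subset <- function(X, y, candidates) {
  path <- list()
  best_fit <- NULL
  best_vars <- NULL
  for (k in seq_along(candidates)) {
    subs <- utils::combn(candidates, k, simplify = FALSE)
    kb_fit <- NULL
    kb_vars <- NULL
    for (v in subs) {
      f <- tryCatch(fit_linear(X[, v, drop = FALSE], y),
                    error = function(e) NULL)
      if (is.null(f)) next
      if (is.null(kb_fit) || f$adj_r2 > kb_fit$adj_r2) {
        kb_fit <- f
        kb_vars <- v
      }
    }
    if (is.null(kb_fit)) break
    path[[k]] <- tibble(step = k, added = paste(kb_vars, collapse = "+"),
                        adj_r2 = kb_fit$adj_r2)
    if (is.null(best_fit) || kb_fit$adj_r2 > best_fit$adj_r2) {
      best_fit <- kb_fit
      best_vars <- kb_vars
    }
  }
  if (is.null(best_fit)) stop("no candidate variable could be fitted",
                              call. = FALSE)
  list(variables = best_vars, fit = best_fit, path = bind_rows(path))
}

#' Leave-one-out cross-validation with coefficient averaging
#'
#' One fold per training year: fit on the remaining years, predict the
#' left-out year (rounded to the nearest day), and record the absolute
#' error.  The final coefficients are the arithmetic mean of the per-fold
#' coefficient vectors; the reported MAE is the mean out-of-fold absolute
#' error.  Both are invariant to the order of years.
#'
#' @param X numeric predictor matrix (already restricted to the selected
#'   variables), one row per year.
#' @param y numeric response.
#' @param years year labels, used in error messages and the fold table.
#' @return list with `a`, `b` (averaged), `mae` and `folds` (tibble
#'   `year, actual, predicted, abs_error`).
#' @export
loocv_average <- function(X, y, years = seq_along(y)) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3) stop("LOOCV needs at least 3 years", call. = FALSE)
  stopifnot(nrow(X) == n, length(years) == n)
  a_folds <- numeric(n)
  b_folds <- matrix(NA_real_, n, ncol(X), dimnames = list(NULL, colnames(X)))
  pred <- numeric(n)
  for (i in seq_len(n)) {
    f <- tryCatch(ols_fit(X[-i, , drop = FALSE], y[-i]),
                  error = function(e) {
                    stop("LOOCV fold leaving out year ", years[i],
                         " failed: ", conditionMessage(e), call. = FALSE)
                  })
    a_folds[i] <- f$a
    b_folds[i, ] <- f$b
    pred[i] <- round(f$a + sum(f$b * X[i, ]))
  }
  list(a = mean(a_folds),
       b = colMeans(b_folds),
       mae = mean(abs(pred - y)),
       folds = tibble(year = years, actual = y, predicted = pred,
                      abs_error = abs(pred - y)))
}

# response column in the seasons table for a mode/criterion pair
response_column <- function(mode, criterion) {
  criterion <- as.character(criterion)
  if (!criterion %in% c("5", "2.5")) {
    stop("criterion must be \"5\" or \"2.5\"", call. = FALSE)
  }
  if (mode == "start") {
    if (criterion == "5") "start_doy_5" else "start_doy_2_5"
  } else "peak_doy"
}

start_column <- function(criterion) {
  if (as.character(criterion) == "5") "start_doy_5" else "start_doy_2_5"
}

#' Search all candidate windows for the best linear model
#'
#' Runs the full regression procedure over every enumerated averaging
#' window: feature vectors (optionally blended after the issue date),
#' forward stepwise selection, LOOCV with coefficient averaging, and the
#' overall F-test gate at `p <= p_max`.  In `mode = "peak"` the window end
#' is each year's observed season start day (criterion-matched) and that
#' start day joins the eight weather means as a candidate feature.  The
#' admissible window with the smallest LOOCV MAE is returned.
#'
#' @param weather weather tibble.
#' @param seasons season dates table ([season_dates()]).
#' @param mode `"start"` or `"peak"`.
#' @param criterion `"5"` or `"2.5"` (cumulative start criterion).
#' @param training_years years used for fitting (>= 4).
#' @param blend optional [blend_config()] applied to post-issue days.
#' @param start_range,end_range window enumeration ranges
#'   (see [enumerate_windows()]); `end_range` defaults to 1-11 March for
#'   start mode and to the per-year season start for peak mode.
#' @param p_max overall F-test gate, default 0.05.
#' @return list of class `window_search` with `best` (a `pollen_lm`) and
#'   `results` (one row per window).
#' @export
search_best_window <- function(weather, seasons, mode = c("start", "peak"),
                               criterion = "5", training_years,
                               blend = NULL,
                               start_range = c("01-01", "02-25"),
                               end_range = NULL, p_max = 0.05) {
  mode <- match.arg(mode)
  if (is.null(end_range)) {
    end_range <- if (mode == "start") c("03-01", "03-11") else "mps-start"
  }
  train <- seasons[seasons$year %in% training_years, , drop = FALSE]
  train <- train[order(train$year), , drop = FALSE]
  if (nrow(train) < 4) stop("need at least 4 training years", call. = FALSE)
  y <- train[[response_column(mode, criterion)]]
  years <- train$year
  windows <- enumerate_windows(start_range, end_range)

  # daily (blended) values per training year over the maximal span needed
  per_year_end <- if (mode == "peak") {
    setNames(train[[start_column(criterion)]], years)
  } else NULL
  span_start <- windows$start_md[1]
  daily <- lapply(seq_along(years), function(i) {
    yr <- years[i]
    end_date <- if (mode == "peak") doy_date(yr, per_year_end[i])
                else md_date(yr, max_md(windows$end_md))
    dates <- seq(md_date(yr, span_start), end_date, by = "day")
    dates <- dates[monthday(dates) != "02-29"]
    cum <- apply(blended_daily_matrix(weather, yr, dates, blend,
                                      training_years), 2, cumsum)
    if (!is.matrix(cum)) cum <- matrix(cum, nrow = 1,
                                       dimnames = list(NULL, WEATHER_COLS))
    list(dates = dates, cum = cum)
  })

  feature_matrix <- function(w_start, w_end_md) {
    out <- matrix(NA_real_, length(years), length(WEATHER_COLS),
                  dimnames = list(NULL, WEATHER_COLS))
    for (i in seq_along(years)) {
      d <- daily[[i]]
      i0 <- match(md_date(years[i], w_start), d$dates)
      i1 <- if (mode == "peak") length(d$dates)
            else match(md_date(years[i], w_end_md), d$dates)
      if (is.na(i0) || is.na(i1) || i1 < i0) {
        stop("window ", w_start, "..", w_end_md,
             " not covered in year ", years[i], call. = FALSE)
      }
      lo <- if (i0 > 1) d$cum[i0 - 1, ] else 0
      out[i, ] <- (d$cum[i1, ] - lo) / (i1 - i0 + 1)
    }
    out
  }

  candidates <- WEATHER_VARS
  results <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    row <- tryCatch({
      # a window can be invalid for peak mode when a year's season starts
      # before the window does; such windows are skipped
      Xw <- feature_matrix(windows$start_md[w], windows$end_md[w])
      if (mode == "peak") {
        Xw <- cbind(start_day = unname(per_year_end), Xw)
        candidates <- c("start_day", WEATHER_VARS)
      }
      st <- forward_stepwise(Xw, y, candidates)
      cv <- loocv_average(Xw[, st$variables, drop = FALSE], y, years)
      tibble(start_md = windows$start_md[w], end_md = windows$end_md[w],
             variables = list(st$variables),
             a = cv$a, b = list(cv$b),
             adj_r2 = st$fit$adj_r2, p_value = st$fit$p_value,
             loocv_mae = cv$mae,
             admissible = st$fit$p_value <= p_max)
    }, error = function(e) NULL)
    results[[w]] <- row
  }
  results <- bind_rows(results)
  ok <- results[results$admissible, , drop = FALSE]
  if (!nrow(ok)) {
    stop("no admissible model: every window failed the p <= ", p_max,
         " gate", call. = FALSE)
  }
  b <- ok[which.min(ok$loocv_mae), ]
  best <- structure(list(
    mode = mode, criterion = as.character(criterion),
    response = response_column(mode, criterion),
    window = list(start_md = b$start_md,
                  end_md = if (mode == "peak") "mps-start" else b$end_md),
    variables = b$variables[[1]],
    a = b$a, b = b$b[[1]][b$variables[[1]]],
    adj_r2 = b$adj_r2, p_value = b$p_value, loocv_mae = b$loocv_mae,
    training_years = years
  ), class = "pollen_lm")
  structure(list(best = best, results = results, n_windows = nrow(windows)),
            class = "window_search")
}

max_md <- function(mds) mds[which.max(md_num(mds))]

#' @export
print.pollen_lm <- function(x, ...) {
  cat("<pollen_lm> ", x$response, ", window ", x$window$start_md, "..",
      x$window$end_md, "\n", sep = "")
  cat("  a = ", format(x$a, digits = 6), "; b: ",
      paste(names(x$b), format(unname(x$b), digits = 4), sep = " = ",
            collapse = ", "), "\n", sep = "")
  cat("  adj R2 = ", round(x$adj_r2, 3), ", p = ",
      format.pval(x$p_value, digits = 3), ", LOOCV MAE = ",
      round(x$loocv_mae, 2), " days\n", sep = "")
  invisible(x)
}

#' Predict a season date from a fitted or loaded linear model
#'
#' Evaluates `a + sum(b_i x_i)` on the year's (blended) window-mean feature
#' vector and rounds to the nearest integer day.  For peak-day models the
#' window end and the `start_day` feature both use `start_day` - the
#' observed start in training, the predicted start at prediction time.
#'
#' @param model a `pollen_lm` (from [search_best_window()] or
#'   [read_model()]).
#' @param weather weather tibble.
#' @param year year to predict.
#' @param blend optional [blend_config()]; post-issue days are blended with
#'   the `training_years` climatology.
#' @param training_years climatology years for blending.
#' @param start_day season start day-of-year, required by peak-day models.
#' @return predicted day-of-year (integer).
#' @export
predict_day <- function(model, weather, year, blend = NULL,
                        training_years = NULL, start_day = NULL) {
  stopifnot(inherits(model, "pollen_lm"))
  end_md <- model$window$end_md
  end_doy <- NULL
  if (identical(end_md, "mps-start")) {
    if (is.null(start_day)) {
      stop("peak-day model needs start_day (observed in training, ",
           "predicted at prediction time)", call. = FALSE)
    }
    end_md <- NULL
    end_doy <- start_day
  }
  x <- window_feature_vector(weather, year, model$window$start_md, end_md,
                             blend = blend, training_years = training_years,
                             end_doy = end_doy)
  if (!is.null(start_day)) x <- c(x, start_day = start_day)
  miss <- setdiff(names(model$b), names(x))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  as.integer(round(model$a + sum(model$b * x[names(model$b)])))
}
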
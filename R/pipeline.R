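# End-to-end orchestration: season metrics -> model fitting on training
# years only -> test-year prediction with the issue-date hindcast ->
# MAE evaluation report.

#' Assemble a pipeline run configuration
#'
#' Train and test years must be disjoint, with training preceding testing
#' (the chronological 80/20 convention: with 15 years, the first 12 train
#' and the last 3 test).
#'
#' @param train_years,test_years inclusive year vectors.
#' @param criteria cumulative start criteria to fit (`"5"`, `"2.5"`).
#' @param targets `"start"`, `"peak"` or both.
#' @param methods `"lr"` (linear regression), `"pm"` (phenological model)
#'   or both.
#' @param blend [blend_config()] used for test-year prediction, or `NULL`
#'   for pure observations.
#' @param lr_start_range,lr_end_range window enumeration ranges for the
#'   regression search (defaults: full 56 x 11 space).
#' @param pm_grid_start,pm_grid_peak phenology calibration grids
#'   (defaults: full grids, see [phenology_grid()]).
#' @param out_dir optional directory for artifacts (models, predictions,
#'   report).
#' @param verbose log selection decisions with `message()`.
#' @return list of class `run_config`.
#' @export
run_config <- function(train_years, test_years, criteria = c("5", "2.5"),
                       targets = c("start", "peak"), methods = c("lr", "pm"),
                       blend = blend_config(),
                       lr_start_range = c("01-01", "02-25"),
                       lr_end_range = c("03-01", "03-11"),
                       pm_grid_start = NULL, pm_grid_peak = NULL,
                       out_dir = NULL, verbose = TRUE) {
  train_years <- as.integer(train_years)
  test_years <- as.integer(test_years)
  if (length(intersect(train_years, test_years))) {
    stop("train and test years must be disjoint", call. = FALSE)
  }
  if (length(test_years) && max(train_years) >= min(test_years)) {
    stop("training years must precede test years", call. = FALSE)
  }
  structure(list(train_years = train_years, test_years = test_years,
                 criteria = match.arg(criteria, several.ok = TRUE),
                 targets = match.arg(targets, several.ok = TRUE),
                 methods = match.arg(methods, several.ok = TRUE),
                 blend = blend,
                 lr_start_range = lr_start_range,
                 lr_end_range = lr_end_range,
                 pm_grid_start = pm_grid_start, pm_grid_peak = pm_grid_peak,
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [run_config()] arguments; year ranges may be
#' written `"2004:2015"`.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  parse_years <- function(x) {
    if (is.character(x) && grepl(":", x)) {
      r <- as.integer(strsplit(x, ":")[[1]])
      seq(r[1], r[2])
    } else as.integer(x)
  }
  blend <- if (isFALSE(y$blend)) NULL else {
    do.call(blend_config, c(list(), y$blend[c("issue_date", "w_obs")]
                            [!vapply(y$blend[c("issue_date", "w_obs")],
                                     is.null, TRUE)]))
  }
  args <- list(train_years = parse_years(y$train_years),
               test_years = parse_years(y$test_years), blend = blend)
  for (k in c("criteria", "targets", "methods", "lr_start_range",
              "lr_end_range", "out_dir", "verbose")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(args$criteria)) args$criteria <- as.character(args$criteria)
  do.call(run_config, args)
}

#' Run the full prediction pipeline
#'
#' Computes the season-dates table, fits every requested model on the
#' training years only, predicts each test year with the configured
#' issue-date blend (peak models receive the same method's *predicted*
#' start day), and reports per-model test MAEs.
#'
#' @param weather weather tibble (or path to a weather CSV).
#' @param pollen pollen tibble (or path to a pollen CSV).
#' @param config a [run_config()].
#' @return list of class `pipeline_result`: `report` (tibble
#'   `method, target, criterion, mae`), `predictions` (per-year table),
#'   `models` (named list), `seasons`.
#' @export
run_pipeline <- function(weather, pollen, config) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(weather)) weather <- read_weather_csv(weather)
  if (is.character(pollen)) pollen <- read_pollen_csv(pollen)
  say <- function(...) if (config$verbose) message(...)
  seasons <- season_dates(pollen)
  missing_years <- setdiff(c(config$train_years, config$test_years),
                           seasons$year)
  if (length(missing_years)) {
    stop("season dates unavailable for year(s) ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  tr <- config$train_years
  need_start <- union(config$targets, "start")  # peak prediction needs it

  models <- list()
  for (crit in config$criteria) {
    key <- gsub("\\.", "_", crit)
    if ("lr" %in% config$methods) {
      for (tg in need_start) {
        say("fitting LR ", tg, " model, ", crit, "% criterion")
        ws <- search_best_window(weather, seasons, mode = tg,
                                 criterion = crit, training_years = tr,
                                 start_range = config$lr_start_range,
                                 end_range = if (tg == "start")
                                   config$lr_end_range else "mps-start")
        say("  chose window ", ws$best$window$start_md, "..",
            ws$best$window$end_md, ", variables ",
            paste(ws$best$variables, collapse = "+"),
            ", LOOCV MAE ", round(ws$best$loocv_mae, 2), " days (",
            sum(ws$results$admissible), "/", ws$n_windows,
            " admissible windows)")
        models[[paste0("lr_", tg, "_", key)]] <- ws$best
      }
    }
    if ("pm" %in% config$methods) {
      for (tg in need_start) {
        say("calibrating PM ", tg, " model, ", crit, "% criterion")
        grid <- if (tg == "start") config$pm_grid_start else
          config$pm_grid_peak
        pm <- calibrate_phenology(weather, seasons, mode = tg,
                                  criterion = crit, training_years = tr,
                                  grid = grid)
        say("  ", pm$n_candidates, " surviving candidates; M = ",
            round(pm$M, 2), ", train MAE ", round(pm$train_mae, 2), " days")
        models[[paste0("pm_", tg, "_", key)]] <- pm
      }
    }
  }

  predict_one <- function(method, target, crit, year) {
    key <- gsub("\\.", "_", crit)
    model <- models[[paste0(method, "_", target, "_", key)]]
    start_day <- NULL
    if (target == "peak") {
      start_day <- predict_one(method, "start", crit, year)
    }
    if (method == "lr") {
      predict_day(model, weather, year, blend = config$blend,
                  training_years = tr, start_day = start_day)
    } else {
      predict_day_phenology(model, weather, year, blend = config$blend,
                            training_years = tr, start_day = start_day)
    }
  }

  preds <- list()
  for (method in config$methods) {
    for (tg in config$targets) {
      for (crit in config$criteria) {
        actual_col <- response_column(tg, crit)
        for (y in config$test_years) {
          preds[[length(preds) + 1L]] <- tibble(
            method = method, target = tg, criterion = crit, year = y,
            predicted = predict_one(method, tg, crit, y),
            actual = seasons[[actual_col]][seasons$year == y]
          )
        }
      }
    }
  }
  predictions <- bind_rows(preds)
  report <- predictions |>
    group_by(.data$method, .data$target, .data$criterion) |>
    summarise(mae = mean_absolute_error(.data$predicted, .data$actual),
              n_years = dplyr::n(), .groups = "drop")

  out <- structure(list(report = report, predictions = predictions,
                        models = models, seasons = seasons),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_artifacts(out, config$out_dir)
  out
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$models)) {
    write_model(result$models[[nm]], file.path(out_dir,
                                               paste0(nm, ".json")))
  }
  readr::write_csv(result$predictions,
                   file.path(out_dir, "predictions.csv"))
  readr::write_csv(result$report, file.path(out_dir, "report.csv"))
  jsonlite::write_json(
    lapply(split(result$report, seq_len(nrow(result$report))), function(r) {
      list(method = r$method, target = r$target, criterion = r$criterion,
           mae = r$mae, n_years = r$n_years)
    }) |> unname(),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(result$seasons, file.path(out_dir, "seasons.csv"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> test-set mean absolute errors (days):\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}
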
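# JSON serialisation of fitted models, and example coefficient sets.

#' Write a fitted model to JSON
#'
#' Works for both linear season models (`pollen_lm`) and calibrated
#' phenological models (`pollen_phenology`).
#'
#' @param model model object.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, c("pollen_lm", "pollen_phenology")))
  x <- unclass(model)
  x$.class <- class(model)[1]
  if (!is.null(x$b)) x$b <- as.list(x$b)
  if (!is.null(x$params)) x$params <- unclass(x$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON file path.
#' @return a `pollen_lm` or `pollen_phenology` object.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  if (cls == "pollen_lm") {
    x$b <- unlist(x$b)
    x$variables <- as.character(x$variables)
  }
  if (cls == "pollen_phenology") {
    x$params <- if (x$mode == "start") {
      start_forcing_params(x$params$F1, x$params$d, x$params$c)
    } else peak_heat_params(x$params$T_D, x$params$Th)
  }
  structure(x, class = cls)
}

#' Example linear season models for paper mulberry in Islamabad
#'
#' Coefficient sets of the four linear season-date models fitted to the
#' 2004-2015 Islamabad paper-mulberry record (start and peak day under the
#' 5% and 2.5% cumulative criteria), shipped as JSON fixtures.  They allow
#' exercising the prediction path without refitting; their coefficients
#' assume the package's fixed units and window conventions.
#'
#' @param name one of `"start_5"`, `"start_2_5"`, `"peak_5"`, `"peak_2_5"`;
#'   `NULL` lists the available names.
#' @return a `pollen_lm`, or a character vector of names.
#' @export
example_model <- function(name = NULL) {
  dir <- system.file("extdata", "models", package = "pollenseason")
  avail <- sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail) stop("unknown example model: ", name, call. = FALSE)
  read_model(file.path(dir, paste0(name, ".json")))
}
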
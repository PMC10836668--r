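#!/usr/bin/env Rscript
# Stage 3: window-searched stepwise linear regression on the training
# years (2004-2015).
#
# For each of the 616 candidate averaging windows (starts 1 Jan-25 Feb,
# ends 1-11 Mar; peak models: 56 starts with the end fixed at each year's
# observed season start), forward stepwise selection by adjusted R^2 picks
# the predictor subset, LOOCV averages the fold coefficients, models with
# overall F-test p > 0.05 are discarded, and the window with the smallest
# out-of-fold MAE wins.

library(pollenseason)

weather <- read_weather_csv("results/data/weather.csv")
seasons <- readr::read_csv("results/seasons.csv", show_col_types = FALSE)
train <- 2004:2015
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

for (mode in c("start", "peak")) {
  for (crit in c("5", "2.5")) {
    ws <- search_best_window(weather, seasons, mode, crit, train)
    key <- paste0("lr_", mode, "_", gsub("\\.", "_", crit))
    cat("\n==", key, "(", sum(ws$results$admissible), "of", ws$n_windows,
        "windows admissible )\n")
    print(ws$best)
    write_model(ws$best, file.path("results/models",
                                   paste0(key, ".json")))
  }
}
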
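#!/usr/bin/env Rscript
# Stage 4: brute-force calibration of the thermal-forcing models on the
# training years (2004-2015).
#
# Start model: all 247,640 combinations of onset (1 Oct-28 Feb), sigmoid
# steepness (-10..-0.25 by 0.25) and threshold (0-40 degC); peak model:
# all 1,681 trigger/base pairs.  Combinations with zero mean forcing or
# relative SD > 50% across years are discarded; the survivor with the
# smallest training MAE is selected and its mean per-year units M become
# the plant's required forcing.

library(pollenseason)

weather <- read_weather_csv("results/data/weather.csv")
seasons <- readr::read_csv("results/seasons.csv", show_col_types = FALSE)
train <- 2004:2015
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

for (mode in c("start", "peak")) {
  for (crit in c("5", "2.5")) {
    t0 <- Sys.time()
    pm <- calibrate_phenology(weather, seasons, mode, crit, train)
    key <- paste0("pm_", mode, "_", gsub("\\.", "_", crit))
    cat("\n==", key, "( grid", pm$grid_size, "->", pm$n_candidates,
        "survivors,", round(as.numeric(Sys.time() - t0, units = "secs"), 1),
        "s )\n")
    print(pm)
    write_model(pm, file.path("results/models", paste0(key, ".json")))
  }
}
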
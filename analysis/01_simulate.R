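#!/usr/bin/env Rscript
# Stage 1: generate the study record.
#
# Simulates a 15-year Islamabad-like daily record (2004-2018): sinusoidal
# mean temperature around 20.3 degC with AR(1) day noise and per-season
# warm/cold offsets, seven further bounded weather variables, and paper
# mulberry pollen released by the thermal-forcing ground truth (onset 31
# Jan, steepness -1, threshold 15 degC; peak trigger 15 degC over base
# 8 degC), peaking at 40,000 grains/m^3.  Writes the CSVs every later
# stage reads, plus the constructed ground-truth season days.

library(pollenseason)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- make_dataset(climate_config(seed = 20040101 %% 2024), truth_params(),
                   noise_cv = 0.15)

write_daily_csv(ds$weather, file.path(out, "weather.csv"), "weather")
write_daily_csv(ds$pollen, file.path(out, "pollen.csv"), "pollen")
readr::write_csv(ds$truth_seasons, file.path(out, "truth_seasons.csv"))

cat("years simulated:", paste(range(ds$years), collapse = "-"), "\n")
cat("weather span:", as.character(range(ds$weather$date)), "\n")
cat("mean ground-truth start day-of-year:",
    round(mean(ds$truth_seasons$start_doy), 1),
    "(~8 March); peak:", round(mean(ds$truth_seasons$peak_doy), 1), "\n")
cat("maximum daily concentration:",
    round(max(ds$pollen$concentration)), "grains/m3\n")
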
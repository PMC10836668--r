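Package: pollenseason
Title: Predicting the Start and Peak of the Spring Pollen Season from
    Daily Weather
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Delimits the main pollen season of wind-pollinated trees from
    daily airborne pollen concentrations (cumulative-percentage start
    criteria and spring peak day) and predicts next season's start and
    peak days from daily weather.  Two complementary approaches are
    implemented: window-searched forward stepwise linear regression with
    leave-one-out cross-validation and coefficient averaging, and
    thermal-forcing phenological models (sigmoid forcing sum for the
    start day, clamped heat sum for the peak day) calibrated by
    brute-force grid search with relative-standard-deviation filtering.
    A synthetic weather and pollen generator with known ground-truth
    phenological parameters makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    lubridate,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
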
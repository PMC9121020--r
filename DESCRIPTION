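Package: growthmedia
Title: Growth-Curve Kinetics and Defined-Medium Design for Lactic Acid
    Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a nested family of sigmoidal growth models (Logistic,
    Richards, logistic-with-lag, Baranyi-Roberts) to plate-reader optical
    density time series, selects the best model by the Bayesian information
    criterion, and derives kinetic summaries (lag phase, maximum specific
    growth rate, minimum doubling time, maximum density, area under the
    curve). Simulates two-strain Lotka-Volterra competition from
    monoculture fits. Classifies chemically defined medium components as
    essential, stimulatory or non-essential from single-omission
    experiments and composes minimal defined media. Includes a synthetic
    plate-reader data generator so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
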
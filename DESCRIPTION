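Package: rtquic
Title: Analysis of Real-Time Quaking-Induced Conversion (RT-QuIC) Plate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing real-time quaking-induced conversion
    (RT-QuIC) seed-amplification assays read out by thioflavin T (ThT)
    fluorescence. Implements per-plate positivity thresholds (baseline mean
    plus a multiple of the pooled standard deviation), replicate-based
    sample calling (at least two of four wells crossing), per-well kinetic
    metrics (RFU_max/RFU_initial ratio and lag phase), endpoint-dilution
    titration along serial ten-fold dilution series, and cohort
    summarisation. Includes a synthetic plate-kinetics generator (single-hit
    Poisson conversion with logistic ThT growth curves) with known ground
    truth, so every stage of the pipeline can be validated end to end, and
    a command-line interface chaining simulate, call, titrate and summarise
    steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
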
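Package: pcmflight
Title: Degree-Day Flight Phenology Models for Codling Moth from Pheromone
    Trap Captures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds and compares logistic flight-phenology models of codling
    moth (Cydia pomonella) from pheromone-trap captures and daily
    temperatures: degree-day accumulation with lower and upper thresholds,
    biofix detection from sustained trap captures, partitioning of captures
    into generation flights under constrained or unconstrained degree-day
    cutoffs, logit-linear fitting of cumulative-emergence curves, ANCOVA
    comparison of fitted curves (including against the PETE reference
    model), validation with confidence and prediction bands, and a
    trap-capture simulator for exercising the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
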
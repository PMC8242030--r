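Package: rhythmsync
Title: Simulation and Quantification of Chemically Synchronized Gene
    Expression Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying chemically driven synchronization of gene
    expression across isolated microbial communities. Provides a
    rate-dependent hysteretic stochastic-switch simulator for fluorescent
    reporter dynamics under antiphase salicylic acid / auxin rhythms
    (including a killer/sensitive two-strain consortium mode with
    toxin-induced period doubling), a trace-quantification pipeline
    (growth normalization, detrending, Savitzky-Golay smoothing, peak
    detection, response precision, phase drift, synchronization fraction,
    autocorrelation and power spectra, period-doubling ratios), and
    four-parameter Hill dose-response fitting. A synthetic-data generator
    emulates microfluidics time-lapse recordings so that every pipeline
    stage is testable without external data.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
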
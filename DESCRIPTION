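Package: tcrecruit
Title: Thalamocortical Recruitment Analysis of Epileptiform Discharges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how focal neocortical epileptiform
    discharges recruit thalamus in paired two-photon calcium imaging and
    whole-cell electrophysiology recordings. Implements spike-onset
    inference from calcium fluorescence under a first-order autoregressive
    model, population and membrane-potential discharge detection,
    cross-area discharge matching with coupling-reliability (CR) and lag
    statistics, threshold-aligned CR timelines, fractions of cells
    correlated with a remote voltage trace, a permutation-based
    signal-stationarity filter for bleaching artifacts, distance-binned
    pairwise correlation profiles, and cortico-thalamic discharge-intensity
    correlation. A synthetic two-area slice simulator with full ground
    truth makes every stage testable without experimental data.
License: MIT
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
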
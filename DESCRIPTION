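Package: apcmorph
Title: Annual Percent Change Statistics for Longitudinal Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for two-visit longitudinal morphometry
    studies. Annualizes per-region change under a multiplicative
    exponential growth/decay model (annual percent change, APC), screens
    subjects with a group-homogeneity quality-assurance rule, compares
    groups per region with two-sample t-tests, corrects for multiplicity
    with Bonferroni, Benjamini-Hochberg and Storey-Tibshirani q-values
    (including pi0 estimation and applicability diagnostics), and
    correlates morphometric change with cognitive decline. Ships a
    synthetic two-group atrophy cohort generator with ground truth for
    power, calibration and false-discovery-rate experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
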
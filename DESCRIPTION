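Package: bmpkin
Title: Kinetics and Dose-Response Analysis for Biochemical Methane Potential Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing biochemical methane potential (BMP)
    assays with additive dosing, as produced by automatic methane potential test
    systems. Computes theoretical ultimate methane and biogas potentials from
    elemental (CHONS) composition via the Buswell-Mueller stoichiometric balance,
    schedules multi-feed assays with a first-order inoculum-carbon depletion model,
    segments cumulative methane curves into feeding phases, fits modified-Gompertz
    and first-order kinetic models with standard goodness-of-fit diagnostics, models
    whole-experiment cumulative yield with ARIMA order selection over a bounded grid,
    and compares doses through a relative-increase statistic. Includes a synthetic
    multi-reactor experiment generator for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    zoo,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
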
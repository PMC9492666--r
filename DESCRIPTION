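Package: synergyscreen
Title: Drug-Combination Synergy Screening and Median-Effect Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ferroptosis-inducer drug-combination
    screens: normalization of plate-reader viability signals to
    fraction-affected values, Synergy Index scoring with a two-inducer
    hit-calling rule, Chou-Talalay median-effect fitting with Combination
    Index computation at arbitrary effect levels, IC50 shift and
    drug-tolerance metrics, and caliper-based xenograft tumor-growth
    inhibition statistics. Includes a synthetic-data module that generates
    screen plates with planted synergistic compounds, constant-ratio
    combination dose-response series, and xenograft growth trajectories,
    each with ground-truth sidecars for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
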
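Package: conflictedu
Title: Local Armed-Conflict Exposure and Girls' Schooling: Simulation,
    Linkage, Fixed-Effects Estimation and Mortality Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for estimating the effect of nearby
    armed conflict during primary-school ages (6-12) on years of schooling
    measured in late adolescence (15-18), in the style of georeferenced
    survey analyses that join DHS-like survey clusters to UCDP-like violent
    event records. Provides a synthetic microdata generator with planted
    effects, great-circle distance-band exposure linkage (25/50/75/100 km),
    eligibility filtering and survey-weight construction, weighted linear
    and logistic fixed-effects regression with cluster-robust (CR1)
    inference via alternating-projection absorption, location-heterogeneity
    splits (urban/rural, wealth and older-female-education quartiles,
    gender-gap median split, region), and a counterfactual excess under-5
    mortality calculation that propagates schooling-loss and
    mortality-gradient confidence bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    sandwich,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
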
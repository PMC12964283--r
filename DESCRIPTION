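Package: allohealth
Title: Allometric Coordination of Population and Healthcare Resource Supply
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how a city's medical and healthcare resource
    supply scales with its permanent resident population. Builds an
    entropy-weighted composite supply index from institutions, hospital beds
    and doctors; estimates allometric scaling exponents by log-log least
    squares, per year across cities (vertical) and per city across years
    (horizontal); classifies exponents into a six-level allometric typology
    around the b = 0.85 coordination benchmark and tracks between-period
    transitions; decomposes drivers of the per-city exponent with boosted
    regression trees (relative influence and marginal-effect profiles); and
    ships a seeded synthetic city-panel generator plus a packaged reference
    exponent schedule so the whole pipeline is testable without yearbook
    data. Includes exact Fisher-Jenks natural-breaks binning for map-ready
    exports and an end-to-end reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
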
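Package: feedlotNE
Title: Performance-Based Dietary Net Energy and Carcass Analysis for
    Pen-Fed Feedlot Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing pen-level feedlot growth and carcass
    records from randomized complete block finishing trials.  Computes
    carcass-adjusted growth performance with hospital-pen feed
    crediting, back-solves observed dietary net energy for maintenance
    and gain from pen performance via the quadratic energy-balance
    solution, values test ingredients by the replacement technique,
    derives carcass metrics (dressing percentage, USDA calculated yield
    grade, retail yield, estimated empty-body fat and adjusted final
    body weight), and fits pen-level randomized-complete-block and
    binomial grade-distribution models with least-squares means and
    compact letter displays.  Includes a synthetic-study generator whose
    forward model is the same energy system, so that the full pipeline
    can be exercised and calibrated without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    jsonlite
Config/testthat/edition: 3
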
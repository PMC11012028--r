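Package: tdascea
Title: Cost-Utility Analysis of a Structured Autism Diagnostic Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A decision-analytic model comparing a structured diagnostic
    scale for autism spectrum disorder (ASD) in young children against
    standard clinical diagnosis, from a societal perspective. Couples a
    diagnostic-phase decision tree with a lifetime Markov cohort model over
    ASD severity states, with age-dependent background mortality, annual
    discounting, incremental cost-effectiveness ratios, one-way (tornado)
    and probabilistic sensitivity analyses, cost-effectiveness
    acceptability curves, and scenario analysis. Includes synthetic-data
    generators for life tables, chart-review severity transitions, and
    cost/utility surveys so the full pipeline can be exercised and
    parameter recovery tested without access to the original records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
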
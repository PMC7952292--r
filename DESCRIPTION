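Package: eqvalid
Title: Psychometric Validation of Paired EQ-5D-3L and EQ-5D-5L Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating the EQ-5D-5L descriptive system against the
    EQ-5D-3L in general-population surveys where both instruments were
    administered to the same respondents. Implements feasibility (missing-data)
    assessment, 3L-to-5L redistribution tables with Janssen inconsistency
    classification, ceiling-effect comparison, Shannon informativity and
    evenness with analytic confidence intervals, value-set based index
    scoring, known-groups and convergent validity, and a model-based
    construct-validity procedure that compares internal and held-out error
    distributions of a random-forest "theoretical model" of the index value.
    Includes a calibrated synthetic-population generator emulating a Polish
    adult general-population survey so the full pipeline is testable without
    access to survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
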
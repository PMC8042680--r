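Package: gcross
Title: Generalizability and Decision Studies for Fully Crossed Rating Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component analysis of balanced, fully crossed
    person-by-task-by-rater rating designs, as used in simulation-based
    performance assessment. Estimates the seven variance components of the
    two-facet random model by ANOVA expected mean squares (a G study),
    projects them onto hypothetical designs to obtain relative and absolute
    error variances and generalizability coefficients (D studies), computes
    scenario/rater descriptives and inter-rater and inter-task correlations,
    and provides a seeded simulator of crossed rating data with known
    variance structure for parameter-recovery experiments. Includes a
    pipeline runner and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
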
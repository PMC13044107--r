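Package: pgxpop
Title: Population-Level Pharmacogenomic Recommendation Frequencies and
    Cross-Population Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Turns per-individual star-allele diplotype calls for CYP2D6,
    CYP2C19, CYP2B6 and SLCO1B1 into harmonized drug-recommendation
    categories (activity-score binning for CYP2D6, CPIC-style
    diplotype/phenotype lookup tables for the other genes, including the
    two-gene sertraline rule), selects an analysis cohort by genetic-ancestry
    thresholding, aggregates de-identified records into a query-ready cohort
    store, and compares recommendation-category frequencies between
    populations using Wilson score intervals, risk differences with Wald
    intervals, two-proportion z-tests and Benjamini-Hochberg false discovery
    rate control. A synthetic-cohort generator draws Hardy-Weinberg
    diplotypes and admixture fractions so the whole pipeline is testable
    without access to individual-level genomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
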
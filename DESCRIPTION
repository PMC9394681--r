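Package: lxtrial
Title: Line by Tester Trial Simulation and Combining-Ability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of multi-environment line by tester
    maize trials with derived provitamin A carotenoid traits. Provides a
    validated plot-level field-book data model with delimited-text input and
    output, a synthetic multi-environment trial generator with known general
    and specific combining-ability (GCA/SCA) structure and a yield-carotenoid
    dilution correlation, the combined line by tester analysis of variance
    with Baker's predictability ratio, entry-mean repeatability and
    proportional source contributions, method-of-moments variance components,
    GCA/SCA effect estimation with standard errors, standard heterosis against
    a reference hybrid, genotypic and phenotypic trait correlations, and
    per-tester genetic variances for tester evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
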
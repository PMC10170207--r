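Package: gencontrib
Title: Expected Genetic Contributions from Genealogical Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates per-year expected individual genetic contributions
    (IGC) to a local gene pool from genealogical pedigrees with migration,
    detects cohort-level stabilization of those contributions, and
    quantifies how fitness proxies (lifespan, lifetime reproductive
    success, adult-surviving offspring, grandoffspring) predict stabilized
    contributions via hierarchical zero-inflated beta regression with
    Bayesian R-squared and probability-of-direction inference. Includes an
    individual-based demographic simulator of two-parish historical human
    populations and a gene-dropping Monte-Carlo oracle for validating
    expected contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
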
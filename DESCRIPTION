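Package: moralconcord
Title: Agreement of Moral-Argument Applicability Across Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring how well different populations agree on
    which moral arguments apply to which moral opinions. Estimates
    argument applicability scores (the proportion of respondents who tick
    an argument of a given moral concern as applying to a given issue
    position) from two-sided argument-attribution survey responses,
    quantifies between-population agreement with Lin's concordance
    correlation coefficient, and tests the null hypothesis of perfect
    population-level agreement with a pooled-sample random-split
    resampling procedure. Includes a synthetic survey generator with
    known ground truth so every stage of the pipeline can be validated
    without access to raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
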
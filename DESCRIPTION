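Package: ancovapower
Title: Exact Inference and Power for Two-Group ANCOVA with Random Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact inference and power analysis for the standard two-group,
    one-covariate analysis of covariance under the bivariate-normal
    (random-covariate) model. Computes the adjusted-mean F/t test, standard
    error and confidence interval from raw data; exact statistical power
    under controlled, randomized and observational designs via the
    mixture-of-noncentral-F distribution of the test statistic; power of
    gain-score and covariate-ignoring comparator analyses; and seeded Monte
    Carlo simulation of rejection rates as an internal oracle.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
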
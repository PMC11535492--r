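Package: diagpair
Title: Compare Two Binary Diagnostic Tests from Paired Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Descriptive and inferential statistics for comparing two binary
    diagnostic tests evaluated against a gold standard on the same subjects.
    Computes sensitivity, specificity, predictive values, likelihood ratios,
    prevalence and Youden indices with modern confidence intervals (a
    midpoint-modified Wilson interval for proportions and a closed-form
    approximation to the score interval for likelihood ratios), and performs
    global-then-individual hypothesis testing for each metric family with
    multiplicity control. Includes flexible recoding of positive/negative
    result labels, a plain-language interpreter, broom-style tidiers, ggplot2
    visualisation and a correlated paired-multinomial simulator for coverage
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
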
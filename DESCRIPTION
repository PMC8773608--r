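Package: samediff
Title: Same/Different Magnitude-Comparison Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for same/different magnitude-comparison experiments on
    visual duration and numerosity: log-spaced stimulus design and session
    scheduling, a generative ideal-observer simulator (with heart-rate traces
    for treadmill-running protocols), Gaussian psychometric fitting on a log
    magnitude axis with point-of-subjective-equality (PSE), bias and Weber
    fraction extraction, and the accompanying inference machinery (bootstrap
    Z-tests on fitted peaks with Bonferroni correction, paired t-tests with
    Cohen's d, default JZS Bayes factors, median-split and precision-correlation
    analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
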
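Package: condiag
Title: Confounder Diagnostics for Repeated-Measures Transcriptome Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostic workflow for uncontrolled confounding factors in
    expression matrices from designs with multiple consecutive samples per
    individual: sample-composition signatures via variance screening, Ward
    clustering, seeded cluster extraction and per-individual self-organizing
    maps; time-of-day (circadian) screens by per-individual fold-change range
    and low-variance tails; handling/biopsy-stress detection through biopsy
    re-labeling and a mixed linear model with a permutation-based shrinkage Fs
    test and Storey-Tibshirani q-values; individual-effect selection from
    random-intercept predictions; overlap and hypergeometric
    over-representation reporting against differential-expression scans; and a
    synthetic-data generator that plants each confounder class with ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
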
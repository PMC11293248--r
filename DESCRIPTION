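Package: dnbtip
Title: Dynamic Network Biomarkers and Tipping-Point Detection for
    Time-Course Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the critical transition preceding a qualitative state
    change in replicated time-course gene-expression data via the dynamic
    network biomarker (DNB) criticality index (within-group standard
    deviation and correlation rising while coupling to the background
    falls), including dominant-group search, permutation significance,
    differential-expression screening with fuzzy c-means temporal
    clustering, four-criteria gene prioritization, focal-gene correlation
    subnets around the tipping point, and a synthetic-data generator with
    a planted transition for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
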
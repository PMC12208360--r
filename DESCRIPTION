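Package: codatime
Title: Compositional Multilevel Analysis of Work-Time Physical Behaviours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the composition of work time spent in
    sedentary behaviour, light physical activity and moderate-to-vigorous
    physical activity across nested organisational levels (institution,
    team, worker). Provides isometric log-ratio (ilr) and pivot coordinate
    transformations for three-part behaviour compositions, multiplicative
    zero replacement, validity filtering and compositional aggregation of
    daily accelerometer records, restricted-maximum-likelihood variance
    component analysis and linear mixed models with nested random
    intercepts, translation of pivot-coordinate coefficients into
    percentage changes, back-transformed prediction curves for ternary
    display, and a seeded hierarchical synthetic-data generator emulating
    a multi-site occupational time-use study.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
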
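Package: netqdiag
Title: Inconsistency Diagnostics for Fixed-Effects Network Meta-Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diagnostic toolkit for fixed-effects network meta-analysis of
    contrast-level study data. Fits the consistency model by two-stage
    generalized least squares, computes the design-level hat matrix that
    shows which direct comparisons drive each network estimate, decomposes
    the network Cochran Q statistic into within-design heterogeneity and
    between-design inconsistency, refits the model with single designs
    detached to localize inconsistency, and renders the clustered net heat
    plot that highlights hot spots of inconsistency. Multi-arm studies are
    supported through per-study covariance blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
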
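Package: crcmirnet
Title: miRNA Synergy Networks and Association Statistics for Colorectal
    Cancer Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the computational analysis of paired
    colorectal tissue miRNA profiles: paired differential miRNA calling,
    per-miRNA target-set pathway enrichment (right-sided hypergeometric test
    with Holm step-down correction and Cohen-kappa term grouping),
    construction of miRNA-miRNA functional synergy networks from shared
    enriched pathways, shared transcription factors, or expression
    correlation, weighted-degree hub scoring, and 2x2 marker-positivity
    association statistics (odds ratio with Woolf confidence interval).
    Includes a synthetic-data generator that reproduces the statistical
    structure the analysis assumes, so every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
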
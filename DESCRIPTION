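Package: risyng
Title: Recursive Integration of Synergised Graph Representations for
    Multi-Omics Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative clustering of sample-matched multi-omics data for
    cancer-subtype discovery. Each omics view is encoded by two graph
    representation matrices, a correlation-kernel Gramian and a shifted
    normalised graph Laplacian, which are fused per view into a beta-weighted
    synergy matrix whose weight is selected by a provisional silhouette scan.
    Views are ranked by relevance and merged by a recursive multi-kernel
    integration that accumulates an accretive eigenbasis; k-means on the rows
    of the final basis yields the sample clusters. Includes the matching
    preprocessing rules (missing-value filter, log transform, variance
    filter), internal and external cluster validity indices, enrichment
    scores, Fisher overlap testing, and a synthetic multi-view generator with
    planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    jsonlite
Config/testthat/edition: 3
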
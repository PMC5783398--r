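Package: herdflow
Title: Origin-Destination Livestock Mobility Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds directed, weighted origin-destination mobility networks
    from livestock movement records and analyses them the way veterinary
    epidemiologists study trade and transhumance systems: descriptive topology
    (degree and link-volume distributions with power-law fits, connected
    components, clustering, diameter, great-circle distance profiles, flow
    summary tables), dominant-flow nodal-region decomposition, monthly
    snapshots with Jaccard-index temporal segmentation into mobility periods,
    persistence-based link classification (backbone, frequent, intermediate,
    occasional), and Quadratic Assignment Procedure (QAP) network correlation
    tests. Includes a synthetic movement-data generator with ground-truth
    labels (two-regime year, heavy-tailed hub attachment, distance decay) so
    every stage can be validated without access to confidential movement
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    geosphere,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
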
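Package: agesync
Title: Spatio-Temporal Association Networks of Age-Related Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects directional gene expression changes across consecutive
    age phases in multiple tissues, tests the significance of cross-tissue and
    cross-phase overlap between the changed gene sets under a hypergeometric
    null, and classifies tissue relationships as synchronous, asynchronous, or
    stochastic. Supports fold-change, two-sample Z-test, MAS5-style composite,
    and two-dataset consensus change criteria; builds per-phase association
    networks and a global four-dimensional (tissue by age-phase) network with
    GraphML export; and ships a planted-structure expression simulator with
    ground-truth records for calibration and power studies, plus an
    end-to-end pipeline that writes reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
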
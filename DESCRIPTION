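Package: leafside
Title: Leaf-Side Phyllosphere Community Assembly Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the balance of dispersal versus host
    filtering between the upper and lower surfaces of leaves in
    phyllosphere bacterial communities. Implements the Sloan neutral
    community model fit to occupancy-abundance data (beta-distributed
    local abundances with a detection limit), abundance-occupancy core
    microbiome selection via cumulative Bray-Curtis contributions, a
    weighted endemism statistic with its regression and paired-test
    machinery, sequential-term PERMANOVA on Bray-Curtis dissimilarities,
    Mantel distance-decay tests, and a ground-truthed synthetic community
    generator for a two-leaf-side, multi-host-species study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    geosphere,
    jsonlite
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
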
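Package: netconsensus
Title: Consensus Between Structural Brain Network Reconstruction Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies agreement between structural connectomes reconstructed
    by two independent tractography pipelines. Builds fiber-density-weighted
    networks from fiber endpoint records, averages repeat scans, merges
    parcellations to a common node scale, thresholds weighted networks across
    all densities with randomized tie-breaking, measures Dice similarity
    against the chance expectation (equal to the network density), bootstraps
    a significance curve over subjects to locate the peak-convergence density,
    and extracts and characterises the resulting consensus network with
    standard binary graph metrics (characteristic path length, clustering
    coefficient, global and local efficiency, assortativity). Includes a
    synthetic cohort generator with a planted core network so the whole
    analysis is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
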
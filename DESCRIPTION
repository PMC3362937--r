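Package: syncmap
Title: Two-Phase Consensus Genetic Mapping by Synchronized Marker Ordering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Builds consensus genetic linkage maps from multiple mapping
    populations (F2, backcross, or recombinant inbred lines) that share a
    subset of markers.  Phase 1 orders markers within each population by
    minimizing the sum of adjacent recombination fractions (an open-path
    traveling-salesperson formulation) with jackknife resampling to assess
    order stability.  Phase 2 finds a single order of the shared markers that
    minimizes the weighted sum of map lengths over all populations, using
    exact tabulation-based enumeration inside delineated conflict regions and
    a guided evolution strategy for larger instances.  Includes a
    mapping-population simulator with configurable missing-data and
    genotyping-error models, cost-of-consensus diagnostics, and integral-map
    export with unresolved unique-marker order represented as loops.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
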
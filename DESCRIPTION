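Package: blobind
Title: Heatwave-Responsive Indicator Taxa from Marine Microbial Time Series
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects prokaryotic indicator taxa responding to a marine heatwave
    from OTU (operational taxonomic unit) count tables. Implements the full
    inference chain for a depth-stratified amplicon time series: Bray-Curtis
    community structure (nMDS ordination, UPGMA clustering, alpha diversity),
    asymmetric indicator-value analysis with permutation testing against a
    pre-heatwave/heatwave partition, ensemble co-occurrence network inference
    with a renormalized permutation null and Brown/Benjamini-Hochberg edge
    significance, connectivity-based indicator filtering, and family-level
    cumulative indicator score (CIS) and connectivity (CIC) summaries. Ships a
    synthetic community generator with planted indicators and co-occurrence
    modules so every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    vegan,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
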
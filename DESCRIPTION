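Package: ieegjack
Title: Robustness of Intracranial EEG Functional Networks to Electrode
    Subsampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds undirected weighted functional connectivity networks
    from multichannel intracranial EEG via band-averaged multitaper
    coherence, computes global (global efficiency, synchronizability,
    transitivity) and nodal (node strength, eigenvector centrality,
    betweenness centrality, control centrality, clustering coefficient)
    graph metrics plus regional control centrality, and quantifies their
    robustness to electrode-contact subsampling: random, contiguous, and
    seizure-onset-zone-targeted/sparing removal schemes; reliability and
    rank-stability statistics; agreement measures and their association
    with distance from the onset zone; cohort-level Friedman and
    Dunn-Sidak tests; and patient-specific jackknife confidence sets and
    intervals for network localizations. Includes a synthetic-data module
    generating recordings with known block-coupled coherence structure so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    signal,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
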
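Package: ntefbn
Title: Directed Functional Brain Networks from Normalized Transfer Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates directed functional brain networks from multichannel EEG
    using normalized transfer entropy (plug-in transfer entropy with shuffled
    surrogate bias correction, scaled by the target's conditional entropy).
    Provides a synthetic EEG cohort generator with known state-dependent
    directed coupling, FIR preprocessing (band and notch filtering, baseline
    removal, epoching, amplitude-based epoch rejection), graph-theoretic
    characterization of the resulting digraphs (connectivity density, 3-node
    motif census, directed clustering, characteristic path length, small-world
    index against degree-matched random networks, node strength), hemisphere
    and region information-flow statistics, and novice/expert classification
    with wrapper sequential forward feature selection over five classifiers.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    igraph,
    MASS,
    class,
    e1071,
    rpart,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
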
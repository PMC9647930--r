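Package: epinetml
Title: In Silico Neuronal Networks and Electrophysiological Classification
    of Sodium-Channel Mutation Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates small two-dimensional networks of conductance-based
    (Hodgkin-Huxley type) neurons with Tsodyks-Markram short-term synaptic
    plasticity under three genetic classes (healthy, global sodium-channel
    gain-of-function, inhibitory sodium-channel loss-of-function), extracts a
    fixed panel of 92 electrophysiological features per simulated subject
    (firing rate, minimum embedding dimension, multiscale entropy, waveform
    shape, and transfer-entropy functional connectivity, each with spatial
    gradient summaries over the electrode lattice), and classifies subjects by
    genetic class with five machine-learning methods plus a
    product-of-error-probability ensemble rule.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    rpart,
    xgboost,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
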
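Package: ssm6mA
Title: Selective State-Space Sequence Models for DNA N6-Methyladenine
    Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts N6-methyladenine (6mA) status of the central adenine
    of fixed-length DNA windows with a multi-scale selective state-space
    (Mamba-style) sequence classifier. Each scale branch stacks layers that
    combine position-specific linear filters (one filter bank per sequence
    position) with an input-dependent, zero-order-hold discretized state-space
    recurrence; the three scales are fused by softmax-normalized learnable
    query vectors and classified by a small fully connected head. The package
    provides FASTA data handling in the paired positive/negative benchmark
    layout, a planted-motif synthetic benchmark generator, k-fold
    cross-validated training with early stopping, confusion-matrix and ROC
    metrics, ablation harnesses (shared vs position-specific filters,
    single- vs multi-scale), and interpretation utilities (position-wise
    feature-intensity profiles, penultimate-layer embeddings, per-position
    nucleotide enrichment). The numerical core (forward/backward passes and
    the Adam optimizer) is implemented in C++ via RcppArmadillo.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
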
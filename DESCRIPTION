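Package: fuseAE
Title: Feature-Level Multi-Omics Integration with Multi-View Autoencoders
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature-level integration of multi-modality data with
    fully connected autoencoders for classification and survival
    endpoints. Implements a single-modality autoencoder with a
    task-specific head, a concatenation autoencoder (ConcatAE) that
    preserves modality-unique (complementary) information by
    concatenating per-modality latent features, and a cross-modality
    autoencoder (CrossAE) that enforces consensus by reconstructing
    each modality from the other modalities' latent features before
    element-wise averaging. Survival endpoints are trained with the
    Cox negative log partial likelihood and evaluated with Harrell's
    concordance index. Includes the full preprocessing stack
    (missing-feature removal, log2(X+1), train-fitted min-max
    scaling, top-variance selection, PCA) with stratified four-fold
    60/15/25 cross-validation, a paired two-view noisy-image
    simulation, and a synthetic multi-omics survival generator with
    controllable consensus and complementary latent structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
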
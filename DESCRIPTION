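Package: umint
Title: Unsupervised Modular Neural Network for Single-Cell Multi-Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates paired single-cell omics modalities (for example RNA
    with antibody-derived tags, or RNA with chromatin accessibility) into one
    low-dimensional embedding using a modular autoencoder: each modality has
    its own sparsely-connected encoder module, the modules are fused at a
    shared bottleneck layer, and a mirrored decoder reconstructs every
    modality. Includes matched dense autoencoder baselines (AE, denoising AE,
    sparse AE), closed-form trainable-parameter accounting, clustering and
    reconstruction evaluation metrics (adjusted Rand index, Fowlkes-Mallows
    index, silhouette, Davies-Bouldin, overall reconstruction score), standard
    single-cell preprocessing (library-size normalization, log transform,
    highly variable feature selection, centered log-ratio transform, feature
    scaling), and a synthetic paired multi-omics generator with known cluster
    structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    cluster,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
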
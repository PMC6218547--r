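Package: dropimpute
Title: Masked-Autoencoder Imputation of Dropout Zeros in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes technical dropout zeros in single-cell RNA-seq count
    matrices with an overcomplete single-hidden-layer autoencoder whose
    reconstruction loss is evaluated only at observed (non-zero) entries,
    trained full-batch with RMSProp. Includes the standard preprocessing
    pipeline (gene filtering, median library-size normalization,
    high-dispersion gene selection, log transformation), a clustered
    negative-binomial count simulator with expression-dependent dropout,
    evaluation protocols (masking-based expression recovery, k-means adjusted
    Rand index, within-cluster coefficient of variation, PCA silhouette
    separability, bulk-binned zero-fraction analysis), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    cluster,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
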
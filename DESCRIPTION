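Package: gatsage
Title: Per-Cancer-Type Driver Gene Prediction with Graph Attention and
    GraphSAGE over Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts cancer driver genes one tumor type at a time by
    integrating genomic, transcriptomic and epigenomic features with
    protein-protein interaction (PPI) network structure. Builds a fixed
    36-column per-gene feature matrix (mutation frequency, variant allele
    fraction, mutational-heterogeneity covariates, base-conversion counts,
    copy-number variation rate, expression fold change, differential
    expression flag, Grubbs-test outlier counts, methylation fold change,
    mutation-outlier bipartite-graph features and network centralities),
    assigns semisupervised positive/negative/unlabeled gene labels, and
    fits a graph neural network composed of one graph-attention layer and
    two GraphSAGE layers with a two-way softmax head, trained with Adam on
    cross-entropy over labeled genes. Ships an 11-point interpolated
    average-precision evaluator, a cell-proliferation association test for
    vetting newly predicted drivers, and a synthetic multiomics generator
    with planted driver signal so the full pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
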
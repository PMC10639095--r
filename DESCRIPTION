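Package: GraphMaskAE
Title: Self-Supervised Masked Graph Autoencoding for Gene Classification on
    Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pretrains a graph neural network autoencoder by reconstructing
    randomly masked node features on a featured protein-protein interaction
    network, then fine-tunes the encoder for transductive node classification
    (e.g. cancer gene, essential gene and healthy-driver gene identification)
    and for graph-level classification of disease subnetworks. Provides GCN
    and GIN message-passing layers with residual links and layer
    normalization, a scaled cosine reconstruction loss, a weighted masked
    binary cross-entropy for imbalanced transductive learning,
    precision-recall evaluation with cross-validation fold reporting, readers
    and writers for edge-list/feature/label tables, and a synthetic
    featured-graph generator with planted two-class structure so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    e1071
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-internal.R'
    'graph-io.R'
    'synthetic-data.R'
    'gnn-core.R'
    'gnn-train.R'
    'masked-pretraining.R'
    'evaluation.R'
    'task-finetuning.R'
    'cli.R'
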
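Package: sebiograph
Title: Few-Shot Semi-Supervised Learning on Biomedical Graphs via Knowledge Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Episodic few-shot node classification and link prediction on banks of
    biomedical graphs. A gated two-layer graph-convolutional encoder maps nodes of
    each graph into a shared metric space; class prototypes are built by a one-layer
    graph convolution over intra-class relation graphs followed by max pooling; a
    hierarchical coarsening gate modulates globally shared encoder weights per graph;
    and a graph-autoencoder reconstruction term regularizes the embeddings. Training
    is episodic over auxiliary graphs so that the learned metric space transfers to a
    sparsely labeled target graph. Includes a seeded stochastic-block-model generator
    of graph banks with class-conditional Gaussian features, evaluation harnesses
    reporting micro/macro F1 and link-prediction accuracy, and plain-text graph I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
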
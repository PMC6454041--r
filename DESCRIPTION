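Package: n2asvm
Title: Disease Gene Prioritization on Protein Interaction Networks via
    Biased Random-Walk Embeddings, Autoencoder Compression and SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the N2A-SVM pipeline for candidate disease-gene
    prediction on protein-protein interaction (PPI) networks: genes are
    embedded with skip-gram vectors trained on second-order biased random
    walks (the node2vec sampling rule with return parameter p and in-out
    parameter q), the embeddings are compressed with an autoencoder, and a
    support vector machine trained on known disease genes versus sampled
    non-disease genes ranks the remaining genes by calibrated probability.
    Includes random-walk-with-restart, shortest-path-length and
    Euclidean-distance baseline scorers, cross-validated AUROC evaluation
    with ablation variants, a planted-partition synthetic network generator
    for offline testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    e1071,
    optparse,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
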
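Package: neri
Title: Network-Based Prioritization of Differentially Coexpressed Disease Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates undirected protein-protein interaction (PPI) networks
    with two-condition (control/disease) gene expression to prioritize disease
    gene candidates. Starting from a set of seed genes, the seed neighborhood is
    grown to the seeds' direct interactors, all shortest paths between seeds and
    the grown set are enumerated, and paths are selected per gene pair by an
    inversion-maximized Kendall concordance coefficient (W_max) with an epsilon
    tie rule. Genes are scored per condition by a distance-decayed,
    concordance-weighted path membership sum; the two condition scores are
    combined into an intensity X, a relative alteration Delta, and an
    intensity-normalized alteration Delta' obtained by dividing Delta by a
    sliding-window third-quartile power-law envelope fitted on the X axis.
    Includes a synthetic benchmark generator (scale-free network with a planted
    one-condition coexpression module and hub decoys), recovery metrics, ranking
    comparison and replication-overlap utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
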
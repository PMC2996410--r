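Package: phyletic
Title: Gene-Content Phylogenetics from Phyletic Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for gene-content ("phyletic pattern") phylogenetics:
    exact Smith-Waterman local alignment with affine gaps and
    Karlin-Altschul significance, reciprocal-best-hit homology detection
    with length and identity filters, assignment of proteins to
    category-labelled reference ortholog groups, construction of binary
    presence/absence matrices restricted to informational gene
    categories, Euclidean-distance agglomerative clustering into a
    dendrogram with Newick export, and clade-recovery evaluation
    (monophyly and Robinson-Foulds distance). Includes a synthetic
    genome-evolution generator (gene gain/loss Markov process on a
    clade-structured tree plus per-site sequence divergence) so that
    every pipeline stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    igraph,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
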
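Package: virtaxa
Title: Information-Theoretic Genome Distances and Taxonomy for Viruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-based pairwise distances between viral genomes built
    from the variation of information of their genes: translated local
    alignment bit scores are read as mutual information, per-gene distances
    are combined like resistors in parallel, and genome pairs without any
    gene match fall back to a rescaled 4-mer over/under-representation
    variation of information. The combined distance matrix is embedded with
    classical multidimensional scaling and Barnes-Hut t-SNE, clustered by
    density with OPTICS, summarised as a cluster dendrogram, and new genomes
    are placed into an existing clustering with a size-weighted k-nearest
    neighbour classifier. Includes a synthetic corpus generator with known
    family structure, GenBank/FASTA input, tabular alignment-hit input, and
    an end-to-end pipeline with stage caching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    Rtsne,
    ape,
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
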
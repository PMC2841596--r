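Package: specfam
Title: Spectral Clustering of Protein Sequence Similarity Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers protein families and superfamilies from pairwise BLAST
    E-values by spectral clustering of the similarity graph. E-values are
    mapped to evolutionary-relatedness probabilities through a logistic
    model, assembled into a symmetric unit-diagonal affinity matrix, and
    clustered with a normalized-matrix spectral embedding whose dimension is
    chosen automatically from the eigengap. Includes connected-component and
    average-linkage hierarchical baselines, cluster quality statistics (mass
    fraction, weighted modularity, combined F-score against a gold
    standard), hypergeometric term-enrichment assessment with
    Benjamini-Hochberg FDR control, a planted-partition generator for fully
    synthetic end-to-end testing, readers and writers for BLAST tabular,
    FASTA, flat cluster text, XGMML and greyscale heatmap PNG output, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    Biostrings,
    png,
    xml2,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
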
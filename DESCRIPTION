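Package: scnetkit
Title: Marker Genes and Functional Interaction Networks for Single-Cell
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless analysis core for cluster interpretation in single-cell
    RNA-seq experiments. Loads normalized gene-by-cell expression matrices
    (MatrixMarket triples, optionally archived) and cell-annotation categories
    (cluster assignments or cell metadata), computes one-vs-rest differential
    expression per group with the Mann-Whitney U test, selects marker genes
    under configurable fold-change, expression-percentage and false discovery
    rate cutoffs, and builds STRING-style functional-interaction networks: a
    category-level union network over the top markers of all groups plus
    per-group induced subnetworks annotated with differential-expression
    statistics. Also provides matrix pre-processing, UMAP and t-SNE
    embeddings, Leiden and Louvain clustering, plot-ready tables, REST
    clients for the EMBL-EBI Single Cell Expression Atlas and Human Cell
    Atlas data portal with recorded-fixture support for offline use, a
    synthetic-data generator with planted markers for end-to-end validation,
    and a command-line interface mirroring the scripted workflow vocabulary.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    igraph,
    uwot,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
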
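Package: pairtcr
Title: Paired Single-Cell TCR and Gene Expression Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for paired single-cell TCR (scTCR-seq) and gene
    expression (scRNA-seq) data from follicular T cells: clonotype calling from
    filtered contig tables, repertoire diversity and rarefaction, public-clonotype
    ordination, GLIPH-style antigen-specificity grouping of CDR3beta sequences with
    Fisher-exact motif enrichment and V-gene bias testing, annotation transfer from
    a harmonized CDR3beta-antigen reference database, position-weight-matrix scanning
    of a proteome for candidate antigens, and clone-size to gene-expression
    correlation. Ships a synthetic-data generator with planted ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    vegan,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
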
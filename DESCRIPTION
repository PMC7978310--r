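Package: pesubtype
Title: Placental Transcriptome Analysis of Preeclampsia Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for subtype-stratified analysis of
    placental bulk RNA-seq in preeclampsia: marker-gene-based removal of
    cord-blood contamination from raw count matrices, dual-procedure
    differential expression (DESeq2 and edgeR) with intersection or union
    combination per subtype, PCA and Ward clustering of samples,
    hypergeometric gene-set enrichment, curated-list fraction enrichment
    with one-sided Fisher tests and bootstrap standard errors, and
    construction of term-gene and TF-target-pathway bipartite networks.
    Includes a negative-binomial synthetic-data generator with known ground
    truth (implanted subtype-specific differential expression and a
    blood-exclusive contamination marker) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    cluster,
    DESeq2,
    edgeR,
    igraph,
    ape,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
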
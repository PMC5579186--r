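Package: cernascape
Title: Inference and Cross-Disease Comparison of miRNA-Mediated ceRNA Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers competing endogenous RNA (ceRNA) cross-talk networks from
    miRNA-target interaction tables and gene expression profiles using a
    hypergeometric shared-miRNA test with Holm correction followed by a
    positive Pearson co-expression filter. Provides per-network topological
    characterization (power-law degree fits, degree/co-expression trends,
    modularity communities, Dicer-stratified co-expression), cross-network
    comparison (Simpson overlap similarity, conserved core extraction, a
    common/differential/specific hub taxonomy), pathway-anchored module
    discovery via k-clique percolation, and classification of ceRNA pairs
    into within- and between-pathway cross-talks. A synthetic-data module
    generates multi-profile studies with planted ceRNA structure so the whole
    pipeline can be exercised and validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
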
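Package: cryomics
Title: Paired Transcriptome-Proteome Integration Screening with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a three-method integration screen for paired gene and
    protein abundance matrices from matched fresh versus cryopreserved samples:
    per-feature differential calling (pooled t-test, Benjamini-Hochberg FDR,
    fold-change gates), hypergeometric over-representation and co-enrichment
    analysis plus a permutation-based gene set enrichment statistic, a bipartite
    Pearson correlation network between pathway-enriched differential genes and
    proteins, and a two-way orthogonal partial least squares (O2PLS)
    decomposition whose top joint-loading features are integration candidates.
    The three method-specific candidate sets are intersected into a consensus
    report. A synthetic paired-omics generator with known planted truth (effects,
    cross-omics correlated pairs, one enriched pathway, a phenotype-linked
    candidate) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
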
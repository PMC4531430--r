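Package: mirgnet
Title: miRNA-Gene Regulatory Network Inference from Paired Tag-Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate miRNA and gene biomarkers of stem-like
    cancer cell populations from paired deep-sequencing count data and
    infers miRNA-gene and miRNA-gene-pathway regulatory networks. Raw tag
    counts are normalized (TPM for small-RNA tags, RPKM for genes),
    differential expression between each stem/parental pair is assessed
    with an exact Poisson tag-count test with Benjamini-Hochberg FDR
    control, predicted miRNA targets from multiple prediction sources are
    integrated by consensus, anti-correlated miRNA-gene pairs form a
    directed bipartite regulatory network with per-miRNA novel-out-degree
    (NOD) statistics, and candidate target sets are tested for pathway
    enrichment with a one-sided Fisher (hypergeometric) test. A seeded
    synthetic-data generator with known ground truth makes every stage
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
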
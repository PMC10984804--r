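Package: xtissue
Title: Cross-Tissue Co-Expression Networks and Exercise-Response Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a co-expression network shared by skeletal muscle and
    subcutaneous adipose tissue from gene-level RNA-seq counts (trimmed mean of
    M-values normalization, log2 counts-per-million, expression and
    protein-evidence filtering), partitions it into gene communities with the
    Louvain algorithm, tests community eigengenes for tissue-discordant
    exercise regulation with a within-subject Time x Tissue repeated-measures
    ANOVA, and relates community expression to clinical traits via Pearson
    correlation and orthogonal projections to latent structures (OPLS and
    OPLS-DA) with variable importance in projection scores, Monte-Carlo
    cross-validation, permutation testing and AUROC. A negative-binomial
    synthetic-cohort generator with planted community structure, planted
    tissue-discordant time effects and planted trait links provides ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    Matrix,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
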
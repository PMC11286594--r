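Package: graftaxis
Title: Serum-Allograft Axis Discovery from Matched Transcriptomes and Serum Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Derives coregulated gene networks from a bulk kidney-allograft
    transcriptome (coefficient-of-variation gene selection, t-SNE embedding,
    k-means network calling), correlates per-sample network activity with a
    time-matched serum protein panel using Spearman similarity, aggregates
    networks into opposing metabolism (MB) and inflammation (INF) axes,
    extracts HEALTH and INJURY serum protein signatures, and validates them
    against a random-set null and clinical kidney function. Includes a
    synthetic cohort generator with latent axis factors and copula-coupled
    proteins for ground-truth recovery testing, and a cross-cohort network
    reproducibility analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
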
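Package: ceRNAseeker
Title: Competing Endogenous RNA Network Inference with Co-Expression
    Modules and Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end analysis of lncRNA-miRNA-mRNA competing endogenous
    RNA (ceRNA) regulation in paired tumor/normal transcriptome designs:
    counts-per-million normalization and negative-binomial Wald tests for
    differential expression, score/energy filtering of predicted
    miRNA-target interactions, hypergeometric shared-miRNA testing with
    Pearson co-expression confirmation to call ceRNA triplets, weighted
    co-expression module detection with topological overlap and module
    eigengenes, median-split Kaplan-Meier / log-rank / univariate Cox
    survival analysis, and 2^-ddCt qPCR relative quantification. A
    synthetic multi-omics generator with planted ground truth (sponge
    triplets, co-expression modules, prognostic lncRNA, qPCR shifts)
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
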
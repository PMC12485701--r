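Package: scckit
Title: Inference of Functional Sex Chromosome Complement from Bulk Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies the functional sex chromosome complement (XaXi, XaXa,
    X0 by loss of X or loss of Y, XY, and unexpected/ambiguous states) of bulk
    RNA-seq samples from XIST and chromosome-Y marker gene expression tiers,
    and drives the downstream analyses that such calls enable: per-tissue
    differential expression with voom-style precision weights and
    empirical-Bayes moderated t-statistics, cross-tissue consistent gene
    profiles, PLS-DA group-structure maps quantifying convergence of X0
    tumors, Kaplan-Meier / log-rank survival stratification, and a fully
    seeded synthetic multi-tissue cohort generator with planted truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, DifferentialExpression, Survival, Classification
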
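Package: immunosubtypes
Title: Immune-Based Expression Subtype Discovery and Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterization of immune-related tumor subtypes
    from bulk expression cohorts. Provides prognostic screening of
    immune-related genes by univariate Cox regression, consensus subtyping by
    Kullback-Leibler (brunet) nonnegative matrix factorization with
    cophenetic/dispersion/silhouette rank selection, single-sample gene-set
    enrichment (ssGSEA) and formula-defined immune scores (stromal/immune/
    ESTIMATE-style sums, IIS, TIS, cytolytic activity, APM, tumor mutational
    burden, checkpoint/IFN-gamma/CD8 signatures), differential expression with
    preranked GSEA, a random-forest subtype classifier with nested
    cross-validation, subclass mapping between cohorts, topological-overlap
    co-expression modules with hub-gene intersection, mutation landscape
    summaries from MAF files, and a negative-binomial synthetic-cohort
    generator so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    randomForest,
    cluster,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
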
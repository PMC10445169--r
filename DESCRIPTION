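Package: pasmatch
Title: Rank-Based Pathway Activity Scoring for Tumor-Cell-Line Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a rank-truncated pathway activity score (PAS) for
    single-sample gene-set scoring of bulk transcriptomes, L1-penalized
    multinomial selection of cancer-type-predictive pathways, and
    Pearson-correlation similarity with hierarchical clustering for matching
    tumor samples to cell lines. Also provides mature-miRNA composition
    statistics, volcano classification and top-table ranking of
    differential-expression results, three-source miRNA target consensus with
    hypergeometric over-representation statistics, and the supporting
    biostatistics used alongside such studies: Fisher's exact test,
    noncentral t and F power analyses, the 2^-ddCt fold-change method, and
    four-parameter log-logistic IC50 fitting. Seeded synthetic-data
    generators emulate the assumed data structure so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    minpack.lm,
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
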
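Package: funburd
Title: Functional Burden Association Testing for Copy Number Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide functional burden association testing (FunBurd) for rare
    copy number variants. Builds tissue and cell-type gene sets by Top Decile
    Expression Proportion (TDEP), aggregates deletion and duplication burden over
    genes fully encompassed by CNVs, fits per gene-set trait associations with
    grid-wide false discovery rate control, and quantifies functional pleiotropy.
    Downstream analyses include overlap-aware permutation p-values conditioned on
    the Jaccard structure of gene sets (P-Jaccard), between-trait burden genetic
    correlations from shrinkage-adjusted effect-size profiles, constraint-normative
    modelling of pleiotropy, and gene dosage-response classification. A synthetic
    cohort generator with planted ground truth supports end-to-end testing and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
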
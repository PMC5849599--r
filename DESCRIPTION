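Package: lcnectype
Title: Genomic and Transcriptomic Subtyping of Pulmonary Large-Cell
    Neuroendocrine Carcinomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stratify large-cell neuroendocrine lung carcinomas
    (LCNEC) into molecular subgroups from somatic mutation tables, segmented
    copy-number profiles and RNA-seq count matrices.  Implements
    significantly-mutated-gene statistics with an expression filter,
    purity/ploidy estimation and cancer-cell-fraction clonality analysis,
    mutational-signature extraction by Kullback-Leibler non-negative matrix
    factorization over the 96 trinucleotide substitution channels, resampling
    consensus clustering with nearest-centroid subtype classification,
    permutation-based differential expression, mutual-exclusivity testing of
    driver alterations, and a synthetic-cohort generator with known ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
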
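Package: htxtools
Title: Outlier Expression, Fusion Filtering and Rearrangement Integration
    for Tumor RNA-Seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the bespoke computational
    procedures used in integrative transcriptome studies of high-risk
    prostate cancer: median-of-ratios count normalization, per-sample
    outlier-expression calling by the Generalized Extreme Studentized
    Deviate (ESD) test with background-noise subtraction and sequencing
    depth rules, over-representation analysis of outlier gene sets against
    GMT collections, a five-criterion fusion-transcript filtering cascade
    with secondary prioritization and DNA-breakpoint corroboration,
    reconstruction of complex (chromoplexy-like) rearrangement chains from
    breakpoint graphs, and a tandem-duplication caller that integrates
    focal copy-number gains with duplication-orientation junctions to
    estimate per-duplication copies (including sub-clonal events) and call
    a tandem-duplicator genotype. A synthetic-cohort generator with planted
    ground truth makes every stage verifiable without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
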
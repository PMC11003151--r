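Package: ernanet
Title: Enhancer RNA Profiling and eRNA-Mediated Regulatory Network Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies enhancers from replicate H3K27ac peak calls, defines and
    quantifies enhancer RNAs (eRNAs) from strand-specific expression counts,
    calls super-enhancers and tissue-specific features (tau-style specificity
    index), performs hypergeometric and genomic-permutation enrichment tests,
    scans sequences with position weight matrices, and assembles directed
    TF -> eRNA -> gene regulatory networks constrained by co-expression,
    genomic distance, topologically associated domains, GWAS proximity and
    STARR-seq allelic activity. Ships a synthetic multi-omics data generator
    with planted ground truth so every stage is testable end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
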
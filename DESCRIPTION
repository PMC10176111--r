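Package: TEactivity
Title: Transposable-Element and piRNA-Cluster Transcription Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Repeat-aware quantification and differential-transcription
    analysis of transposable elements and piRNA clusters from RNA-seq
    alignments. Provides mapping-quality-filtered read counting over
    RepeatMasker-style annotations, a negative-binomial Wald test with
    median-of-ratios normalization, a stringent double-control consistency
    filter, repeat family-composition chi-square tests against genome
    abundance, genomic-context classification of activated elements,
    uni-/dual-strand piRNA cluster scoring with confidence intervals and
    fold changes over control, ChIP-over-input enrichment profiling across
    feature classes, and a fully seeded synthetic-data generator emulating
    a multi-replicate histone-mutant study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
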
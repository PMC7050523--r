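Package: tnxpress
Title: Transposon Insertion-Site Screening with Outward-Promoter Transposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of transposon directed insertion-site sequencing
    (TraDIS/Tn-seq) screens performed with transposons carrying an
    outward-facing inducible promoter. Reads and writes strand-split
    per-base insertion plots, extracts transposon junctions from SAM
    alignments, calls essential genes from the bimodal insertion-index
    distribution with an exponential+gamma mixture, detects
    condition-dependent enrichment or depletion of insertions in genes and
    their 198 bp flanking windows with a negative-binomial conditional
    exact test, classifies hits as gene inactivation, promoter-driven
    up-regulation, or antisense knockdown, aggregates results across
    conditions into matrices and bipartite networks, scores fitness from
    plate-reader growth curves via incremental AUC ratios, and simulates
    saturating insertion libraries with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    igraph,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
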
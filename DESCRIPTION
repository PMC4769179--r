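Package: retroquant
Title: Transposon Annotation Reconstruction, Expression Quantification and
    Repressive Chromatin Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying transposable-element regulation during
    genome-wide DNA demethylation. Reconstructs whole transposon copies from
    fragmented RepeatMasker annotations using an LTR-internal dictionary and
    assigns each copy an integrity score; quantifies transposon expression
    from multi-mapped reads by hit-count weighting and from unique reads per
    element; normalizes counts (TMM), computes log-CPM with precision
    weights, and calls differential expression with a moderated t-test;
    summarizes LUMA pyrosequencing and whole-genome bisulfite CpG calls over
    genomic compartments and elements, and detects residually methylated
    regions; computes ChIP enrichment per element, composite metaprofiles,
    and classifies repeat families into repressive chromatin categories
    defined by H3K9me3/H3K27me3 occupancy. Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    methods,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    limma,
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
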
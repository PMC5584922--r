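Package: guidescreen
Title: Focused CRISPR Screen sgRNA Library Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch design of sgRNA libraries for focused CRISPR knockout
    screens. Scans exons of a query gene list for canonical NGG protospacer
    sites, annotates every candidate with predicted cleavage efficiency,
    Hsu-style off-target specificity, cross-species conservation, isoform
    commonality and overlap with common SNPs or somatic mutations, then
    selects and ranks guides per gene by a filter-and-rescue procedure whose
    criterion weights are derived dynamically with the CRITIC
    (Criteria Importance Through Intercriteria Correlation) method. Emits
    synthesis-ready oligo tables with negative and positive control guides.
    Includes a seeded synthetic-fixture generator so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
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
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
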
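Package: pseudoexon
Title: Deep-Intronic Pseudoexon Discovery, Annotation and Point-Based
    ACMG Classification from Duo Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing a deep intronic splice variant from a
    whole-genome affected/unaffected duo to a classified pathogenic
    call. Provides an HGVS-style transcript coordinate system with
    intronic offsets, carrier-aware variant prioritization (quality,
    gene panel, population frequency, duo segregation, splice delta
    score), pseudoexon (exonization) consequence derivation with r./p.
    HGVS output, frame and NMD 50-nt-rule prediction, RNA assay
    interpretation (allelic-imbalance ratio-of-ratios, tagging-SNP
    completeness test, selective RT-PCR amplicon lengths), a
    point-based ACMG evidence engine, and seeded synthetic-data
    generators that emulate the full study design for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
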
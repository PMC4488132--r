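Package: floraltc
Title: Time-Course Transcriptomics of Flower Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for time-course transcriptomics of
    Arabidopsis flower development on two-channel common-reference
    microarrays: background correction, loess and A-quantile
    normalization, empirical-Bayes moderated linear models with a global
    F-scan and windowed (2-day) contrasts for differential expression
    calling, k-means co-expression clustering with elbow-based k
    selection, mapping of clusters onto a tissue expression atlas,
    resampling-based enrichment of transcription-factor-bound and
    paralogous gene sets, Fisher exact term enrichment with
    Benjamini-Yekutieli correction, strand-aware assignment of binding
    peaks to genes, and paralog identification by local protein
    alignment with E-value and coverage filters.  A synthetic-data
    generator emulates the full study design (14 time-points, 3
    replicates, planted expression archetypes, planted enrichments and
    paralog families) with a ground-truth table so every stage is
    testable end-to-end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    limma,
    Biostrings,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
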
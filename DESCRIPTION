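Package: regsig
Title: Regulatory Analysis of Tumor Subtype Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives tumor-subtype gene expression signatures by two-class
    Significance Analysis of Microarrays (SAM) with permutation-estimated
    false discovery rate and by quality-threshold clustering under jackknife
    correlation, and interrogates them for regulatory structure: strand-aware
    promoter windows around RefSeq transcription start sites, mapping of
    ChIP-Seq peak calls onto promoters, transcription-factor binding
    enrichment by one-tailed Fisher's exact test and by resampling of random
    gene lists, co-binding counts, spatial colocalization profiles of binding
    events, an anterior-versus-posterior HOX expression switch score, marker
    expression ratios, and a permutation test for mitotic division-angle bias
    near the basal lamina. A synthetic-data module generates annotation, peak
    files, expression cohorts and mitosis records with planted ground truth
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
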
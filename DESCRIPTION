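Package: regulonCoupler
Type: Package
Title: Consensus ChIP-Seq Target Panels and Cohort-Stratified
    Transcription-Factor Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds consensus transcription-factor target panels from ranked
    ChIP-Seq binding-score tables (replicate averaging, top-K selection,
    multi-list membership, ortholog mapping and expression-presence filters,
    union with canonical literature targets), screens TF-target expression
    coupling separately in two tumour cohorts with Pearson correlation and
    Benjamini-Hochberg FDR control, compares significant-gene counts between
    cohorts with Fisher's exact test, compares regulator (receptor and
    corepressor) expression across cohorts with Mann-Whitney U tests and
    Bonferroni correction, derives receptor-to-corepressor log-ratio scores
    with ratio-target correlations, and provides a delta-delta-Ct qPCR
    fold-change utility. A seeded synthetic-data generator emulates
    corepressor-modulated TF-target coupling in two cohorts so the whole
    pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
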
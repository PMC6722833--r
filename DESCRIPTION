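Package: eumir
Title: Small RNA, Degradome and Transcriptome Integration for miRNA
    Discovery in Eucommia ulmoides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for plant miRNA analysis: small-RNA
    read cleaning and ncRNA classification, known-miRNA matching and
    novel-miRNA hairpin evaluation, TPM quantification and
    negative-binomial differential expression between low- and
    high-rubber-content leaf libraries, complementarity-based target
    prediction, degradome (PARE) T-plot construction with CleaveLand-style
    category 0-4 cleavage-site classification, and integration of
    differentially expressed miRNAs and targets into a signed regulatory
    network with hypergeometric pathway enrichment. Includes a seeded
    synthetic-data generator that emulates the statistical structure of
    the sequencing libraries so every stage can be exercised and
    benchmarked against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    MASS,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
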
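Package: xshred
Title: Discovery of X-Linked Repeat CRISPR Targets from Sexed Whole-Genome
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies abundant, X-chromosome-specific, CRISPR-targetable
    sequence repeats from male and female whole-genome sequencing libraries,
    for the design of X-shredding sex-ratio distorters in XX/XY insects such
    as the Mediterranean fruit fly. Implements a canonical 25-mer census with
    chromosome-quotient (CQ) classification, long-read binning with an
    X-specificity index (XSI), Cas9/Cas12a PAM scanning with Hamming
    off-target screening against non-X read bins, and a post-hoc assembly
    audit (contig sex assignment by median gene CQ, kmer-to-assembly mapping,
    tandem repeat-array dissection, region-derived kmer specificity). A
    synthetic-data module generates genomes, sexed short-read libraries and
    male long reads with exact planted ground truth so every stage is
    verifiable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
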
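Package: chromguide
Title: Chromatin-Context CRISPR Guide Pool Design and Screen Dropout Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs single-cutting SpCas9 sgRNA libraries (exactly one
    genomic target, no secondary site within a mismatch tolerance),
    annotates each guide's chromatin context in a fixed window around the
    cut site (ChromHMM state fractions, lamina association, DNaseI and
    H3K9me3 signal, gene context), filters guides into pools that each
    target one defined chromatin state under published threshold rules,
    and analyses pooled-screen dropout counts with control-guide
    median-of-ratios normalization and paired fold changes. Ships a
    synthetic-fixture generator (genomes, tracks, planted guide sites,
    negative-binomial screen counts) so every stage runs at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
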
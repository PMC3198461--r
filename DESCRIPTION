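Package: qualtrim
Title: Content-Dependent Quality Trimming of Illumina FASTQ Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality-based preprocessing of Illumina short reads before de
    novo assembly or mapping. Implements an iterative 3'-end trimming
    automaton that removes low-quality read tails while tolerating short
    interior runs of low-quality bases, a two-stage read approval filter
    (high-quality base fraction and a low-quality floor), paired-end
    processing that routes surviving reads into synchronized paired files
    and an unpaired rescue file, a prefix-based PCR-duplicate filter for
    read pairs, and support for the Sanger (offset 33), Illumina (offset
    64) and early-Solexa (offset 64, log-odds) quality-score dialects.
    Ships a seeded synthetic paired-end read generator emulating the
    exponential 3' error-probability growth of Illumina reads, so the
    whole pipeline is testable without external data, plus a command-line
    interface in exec/.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
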
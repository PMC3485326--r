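Package: freqseq
Title: Allele-Frequency Estimation from Barcoded Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for FREQ-Seq-style amplicon allele-frequency estimation
    from pooled Illumina single-end reads. Designs error-detecting 6-mer
    sample barcodes and the 81-nt bridging primers that carry them, simulates
    reads with the FREQ-Seq layout (barcode, M13f adapter, locus primer,
    diagnostic window) under a per-base substitution error model, demultiplexes
    and assigns reads to alleles with a banded edit-distance aligner, and turns
    the resulting counts into frequency estimates with binomial confidence
    intervals, quadratic bias calibration, pure-sample error rates and
    between-run comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
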
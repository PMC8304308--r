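Package: bsaqtl
Title: Bulked-Segregant QTL-Seq Analysis with Simulation-Based Confidence Bands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Maps quantitative trait loci from bulked-segregant whole-genome
    sequencing of F2 crosses (QTL-seq). Computes per-pool SNP-index and
    delta(SNP-index) statistics from allele depths, smooths them in sliding
    genomic windows, derives a resampling null band for the no-QTL
    hypothesis, and calls QTL intervals where the smoothed statistic escapes
    the band. Also provides interval algebra for intersecting QTL calls from
    independent experiments, a candidate-gene filter cascade (delta
    threshold, codon-level variant effect annotation, cross-accession allele
    patterns), small expression utilities (RPKM, differential-expression
    thresholds, relative qPCR quantification), and a fully parameterised
    synthetic F2-cross generator used to validate the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
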
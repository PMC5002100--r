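Package: sweepscan
Title: Cross-Population Selection-Signature Scans for SNP Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects genomic signatures of recent selection in structured
    populations genotyped on SNP arrays, such as the purebred lines of a
    commercial breeding program. Implements the cross-population extended
    haplotype homozygosity statistic (XP-EHH) with shared-boundary iHH
    integration, an XP-CLR-style cross-population composite likelihood
    ratio scan with LD-based SNP down-weighting, pooled-heterozygosity
    (ZHp) sliding-window scans, SNP quality control with Mendelian-error
    filtering, genetic-map interpolation, cross-method and cross-line
    consensus region calling, haplotype-frequency profiling of candidate
    regions, gene annotation, and a Wright-Fisher forward simulator of
    isolated breeding lines with implanted selective sweeps for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
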
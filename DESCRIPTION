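Package: hapbsa
Title: Bulked Segregant Analysis QTL Mapping for Haplodiploid Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pool-seq bulked segregant analysis (BSA) genetic mapping for
    haplodiploid experimental-evolution designs. Starting from a cross of an
    inbred diploid mother strain to a single haploid male of a resistant
    strain, the package infers which allele the sire transmitted at each of
    his heterozygous sites, computes sliding-window allele-frequency tracks
    and paired selected-minus-control differences, detects quantitative trait
    loci (QTL) with a circular-permutation significance threshold, delineates
    QTL intervals by peak similarity, estimates gene copy number from
    normalized read depth and efficiency-corrected qPCR, and tests the mode
    of inheritance of resistance with probit dose-response models, Stone's
    degree of dominance, and a monogenic goodness-of-fit test. A forward
    simulator of the haplodiploid cross and selection experiment generates
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
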
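Package: xcimaint
Title: Allele-Specific Analysis of X-Chromosome Inactivation Maintenance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies allelic imbalance between the inactive (Xi) and active
    (Xa) X chromosome from SNP-split read counts using the d-score statistic,
    classifies X-linked genes as XCI escape or subjective and as Xist-dependent
    or independent, and tests the association between the two classifications
    with an exact two-by-two test. Also provides the non-allelic expression arm
    (FPKM, median-of-ratios size factors, replicate-consistent differential
    expression calls, common versus lineage-specific DEG scoping, signature
    genes, fold-change CDF comparison) and the peak-annotation conventions used
    for ATAC and ChIP data (RPKM/RPK intensities, consensus and merged peaks,
    TSS-proximal/distal partition, nearest-gene annotation, promoter and
    enhancer YY1 peak classification). A built-in synthetic-data generator with
    known ground-truth labels makes every stage testable without sequencing
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
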
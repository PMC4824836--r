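Package: ascnloss
Title: Allele-Specific Copy-Number Loss and LOH Analysis for Tumor SNP Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates allele-specific copy numbers, aberrant-cell fraction and
    average ploidy from SNP-array log-R-ratio (LRR) and B-allele-frequency (BAF)
    tracks of tumor/normal pairs, calls ploidy-relative copy-number loss and loss
    of heterozygosity, summarizes recurrent loss regions across a cohort, and
    tests gene sets (e.g. STOP and CYCLOPS genes) for association with loss via
    an unweighted rank-based enrichment statistic with permutation and
    random-gene-set empirical null distributions. Includes a synthetic-cohort
    generator with known ground truth so that every stage of the pipeline is
    testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
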
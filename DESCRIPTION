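Package: umrscan
Title: Unmapped-Region Detection of Long-Deletion Candidates from
    Short-Read Whole-Genome Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects unmapped regions (UMRs) - maximal reference intervals
    covered by no mapped read - from coordinate-sorted short-read alignments,
    as candidates for long (structural-variant scale) deletions. Provides
    CIGAR-based reference-span computation, a zero-coverage sweep per
    chromosome, gene-annotation filtering, cohort-level set algebra (union
    UUMRs and common CUMRs), break-point overlap comparison against a known
    deletion catalogue, a probability model for UMRs arising under random
    read placement, and a deletion-planting read simulator that makes the
    whole pipeline testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
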
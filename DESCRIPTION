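Package: trnatail
Title: Mapping tRNA 3'-Tail Cleavage Sites and Scoring PFS Depletion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating RNA-guided cleavage sites near the 3' CCA tail
    of tRNAs from two-condition (target versus non-target) nanopore direct
    RNA-seq coverage, using a per-nucleotide depletion score and per-reference
    z-score statistic, and for scoring randomized protospacer-flanking-sequence
    (PFS) depletion screens from amplicon reads. Includes poly(A)-tail
    trimming, a minimal k-mer seed-and-extend read mapper with SAM import as
    an alternative, anchored 5-mer extraction with quality-based exclusion
    rules, and a synthetic-read simulator with known ground truth so the whole
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    data.table,
    dplyr,
    tibble,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    optparse
Config/testthat/edition: 3
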
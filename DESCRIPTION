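Package: srnapipe
Title: Small RNA and Degradome Sequencing Analysis for Plant miRNA Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for post-sequencing analysis of plant small RNA
    and degradome (PARE) libraries: annotation of small RNA tags by a strict
    priority rule, identification of known miRNAs and prediction of novel
    miRNA hairpins with miRNA* validation, noise-distribution (NOISeq-style)
    differential expression with RPM normalization and zero imputation,
    degradome-supported miRNA target calling with cleavage-site category
    classification (0-4), and detection of 21-nt phased siRNA (PHAS) loci
    with a hypergeometric phasing statistic. Ships a synthetic-data generator
    that emulates multi-library collapsed sRNA tags, degradome profiles and
    phased loci so the whole pipeline is testable end-to-end without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: ViennaRNA (RNAfold on the PATH) for hairpin folding
Config/testthat/edition: 3
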
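Package: contigdedup
Title: Homology-Based Redundancy Removal for De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes redundant contigs from de novo RNA-Seq assemblies by
    selecting, for each reference gene, the contig with the highest BLAST bit
    score, and implements two competitor strategies (longest contig per
    assembler subcomponent, cluster representative) for comparison.  Provides
    readers for the standard interchange formats involved (FASTA, BLAST
    tabular, CD-HIT .clstr, SAM, count tables, GO annotation tables), assembly
    length statistics, RPKM-based differential-expression calling with a
    pseudocounted log2 fold change, and an evaluation framework that scores
    each deduplicated contig set against a gold-standard gene set via
    co-identity of differential calls, fold-change correlation, and GO slim
    term distribution tests (Kolmogorov-Smirnov and per-term Fisher).  A
    synthetic assembly simulator with known truth makes the whole workflow
    testable without external aligners or assemblers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
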
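Package: taxabench
Title: Standardized Benchmarking of Taxonomic Annotation Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for taxonomic classifiers of
    marker-gene and shotgun metagenomic reads. Homogenizes arbitrary NCBI
    taxids or taxon names onto eight fixed ranks (domain to subspecies),
    labels every read at every rank as a true/false positive/negative
    against an expected lineage, aggregates per-rank confusion matrices and
    classification metrics (sensitivity, specificity, accuracy, Matthews
    correlation coefficient, error per query, coverage), builds
    score-ranked coverage-versus-error curves with score cut-offs at target
    error rates, and generates fully self-contained simulated 16S rRNA
    amplicon benchmark libraries (in-silico PCR with degenerate primers,
    linear rank-abundance model, fixed-quality paired reads, shuffled
    true-negative sequences, replicate libraries with a shared reference
    pool) together with a configurable mock annotator for closed-loop
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
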
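Package: pavpan
Title: Pan-Genome Construction and Gene Presence-Absence Variation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds population pan-genomes from per-sample assembled contigs and
    calls gene presence-absence variation (PAV) from sequencing depth over coding
    regions. Implements contig classification against a reference (95/95 rule),
    extraction and de-duplication of non-reference sequence, CDS-coverage-based
    presence calling with the chromosome-Y male-only core rule, Fisher's exact
    cohort comparison with Benjamini-Hochberg FDR and odds ratios, anchor-based
    chromosomal placement of non-reference genes using long-read contigs, and
    SURVIVOR-style multi-caller structural-variant merging with DEL-derived PAV
    cross-validation. Ships a deterministic synthetic-study generator with known
    truth so the whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    data.table,
    withr,
    yaml,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
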
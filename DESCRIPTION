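Package: napchip
Title: ChIP-Seq Motif Occupancy, GC-Landscape Colocalization and
    Binding-Expression Statistics for Bacterial Nucleoid-Associated Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for analysing genome-wide binding of
    GATC-motif nucleoid-associated proteins in high-GC bacteria such as
    Streptomyces. Scans genomes exhaustively for degenerate (IUPAC) motifs
    and accounts for their occupancy by called peak regions; segments the
    chromosome into low-GC regions with sliding windows and measures peak
    colocalization; assigns peak summits to strand-aware promoter windows
    to build per-gene binding tables; computes TPM and rank statistics
    (Mann-Whitney U with exact small-sample p-values, Levene's test) for
    binding-versus-expression bias and spore morphometry; and quantifies
    developmental timing from time-lapse plate image stacks. A seeded
    synthetic-data module generates every input with ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
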
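Package: breakscape
Title: Genome-Wide DNA Double-Strand Break Capture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for DSB-capture sequencing experiments in which
    an adaptor is ligated directly to broken DNA ends so that the 5' end of
    the first mate of each read pair marks a double-strand-break position.
    Provides break-end extraction from aligned paired-end reads with the
    standard flag, fragment-length and duplicate filters; priority-ordered
    genomic feature annotation (TSS, promoter, TTS, gene body, intergenic)
    with breaks-per-megabase densities; expression-decile and gene-length
    stratified break-coverage statistics with paired Wilcoxon signed-rank
    condition comparisons and TSS metaprofiles; per-gene TSS fold-change
    enrichment calling; and a fully deterministic DSB-capture simulator
    (toy genome, expression table, truth-tracked break sets, contaminated
    SAM read pairs) so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
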
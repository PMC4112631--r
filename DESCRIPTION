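Package: adjacoreg
Title: Positional Co-Regulation of Adjacent Genes in Mutant Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and statistical testing of co-regulation among
    chromosomally adjacent differentially expressed genes, built around the
    transcriptome of Arabidopsis topoisomerase VI (TopoVI) subunit B mutants.
    Finds maximal runs of immediately adjacent, sign-concordant deregulated
    genes in a chromosome-ordered gene catalogue; tests their enrichment with
    a matched near-zero fold-change control-gene chi-square test, a binomial
    sign-concordance null, and a label-permutation null. Companion analyses:
    cross-study signed gene-list concordance (overall and strict), Mendelian
    segregation chi-square tests, group summaries with fold effects, and
    prediction of the molecular consequence of a splice-donor mutation
    (intron retention, premature stop, truncated protein). A seeded
    synthetic-data generator produces annotated toy genomes, differential
    expression tables with injected adjacent co-regulated blocks, segregating
    progeny counts, and splice fixtures, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
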
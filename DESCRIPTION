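Package: denovoburden
Title: Burden and Enrichment Analysis of De Novo Coding Variants in Trio Cohorts
Version: 0.1.0
Authors@R: person("DHREAMS", "Analyst", email = "analyst@example.org", role = c("aut", "cre"))
Description: Statistical framework for de novo coding variants called in
    proband-parent trios. Computes per-gene baseline mutation rates from a
    trinucleotide-context rate table, converts them into cohort-level
    expectations (with chromosome X non-PAR adjustment), and tests variant
    burden with one-sided Poisson tests, exact fold-enrichment confidence
    intervals, and a genome-wide per-gene recurrence test. Includes a
    context-, class- and deleteriousness-preserving Monte-Carlo placement
    simulation for cross-disorder gene-set enrichment, expression-stratified
    burden with rank percentiles and ortholog mapping, a target-gene
    expression z-score shift test, a hypergeometric enrichment-map builder,
    and a fully seeded synthetic-data generator (toy exomes, rate tables,
    null and risk-spiked trio cohorts, expression matrices) with ground-truth
    manifests for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
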
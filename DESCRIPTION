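Package: modhub
Title: Module-Connectivity Hub Gene Prioritization in Functional Gene
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate regulator ("hub") genes of a gene module
    within a cell-type-specific functional gene interaction network by a
    per-gene module-connectivity z-score, and validates a candidate hub
    against perturbation RNA-seq results with rank-based and set-overlap
    statistics: a one-sided Wilcoxon rank-sum test of differential-expression
    calls against hub connectivity, Fisher's exact module-versus-DEG overlap
    tests with signed (up/down) variants, Benjamini-Hochberg adjustment, and
    cumulative rank-enrichment curves. Includes a seeded planted-module
    network simulator producing DESeq2-shaped differential expression tables
    whose probability of differential expression increases with connectivity
    to the perturbed hub, and a config-driven pipeline that composes
    simulation, scoring, validation and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
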
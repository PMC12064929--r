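Package: lampid
Title: Diagnostic SNP Discovery and Genetic Identification of Lamprey Ecotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and applying diagnostic SNP panels that separate
    sympatric lamprey ecotypes. Implements a pooled-sequencing F_ST genome scan with
    sliding-window summaries and island detection, proportional candidate-SNP
    allocation and five-SNP panel selection with WRL/WBL allele designation, a
    two-marker genus classifier (Entosphenus vs. Lampetra) and a multi-locus
    percent-WRL ecotype classifier with explicit missing-data rules, genetic versus
    morphological identification concordance audits, collection-level composition
    estimates with percentile-bootstrap confidence intervals and overlapping-CI
    stability tests, and a Mantel permutation test for spatial allele-frequency
    structure. A seeded synthetic-data generator emulates a panmictic population
    whose ecotypes differ only at narrow genomic islands of divergence, so the full
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
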
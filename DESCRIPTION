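Package: eqtloverlap
Title: Cross-Tissue eQTL Overlap with LD Proxies and Power Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the concordance of expression quantitative trait loci
    (eQTL) between two tissues or studies. Harmonizes per-study eQTL result
    lists onto a common gene/exon universe, matches best eSNPs directly and
    through linkage-disequilibrium proxy SNPs (r-squared threshold within a
    distance window), compares the observed overlap to its chance expectation,
    and corrects the raw overlap for the replication study's limited sample
    size via a subsampling power estimate, yielding a power-adjusted overlap
    fraction. Includes a seeded generator of paired-tissue genotype and
    expression data with block LD structure and a known true sharing fraction,
    so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
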
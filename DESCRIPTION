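Package: methscreen
Title: Expression-Methylation-Drug Response Correlation Screens for
    Cancer Cell Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for linking expression of genes affecting DNA
    methylation and demethylation (GMDs) to drug response and to
    epigenome-wide DNA methylation in cancer cell line panels.
    Implements Illumina 450K-style probe quality control (detection
    p-value masking, probe-median filtering, SNP-overlap masking),
    gene-region beta-value averaging over the six standard region
    categories, epigenome-average methylation, stratified Spearman
    correlation screens with Benjamini-Hochberg false discovery rate
    families over explicit test-count products, cis/trans
    classification of expression-methylation correlations, a two-stage
    expression-to-methylation-to-drug screen, and mutation-conditional
    linear regression of drug response. A synthetic panel generator
    with a ground-truth ledger of planted effects makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
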
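Package: tmgblup
Title: Text-Mined Gene-Based SNP Panels for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction with genomic-feature partitioned SNP panels
    derived from literature text mining. Extracts gene symbols from abstract
    corpora by dictionary matching, maps mined genes (and their intergenic
    flanks) to SNP panels, builds VanRaden genomic relationship matrices for
    arbitrary SNP subsets, estimates variance components by average-information
    REML with one or two genomic random effects, solves single- and two-GRM
    GBLUP mixed-model equations, runs leave-one-chromosome-out mixed-model
    association scans, and evaluates prediction accuracy by k-fold
    cross-validation against an evenly-spaced control panel. Includes a
    synthetic-data generator (genotypes, feature-enriched phenotypes, and
    symbol-planted abstract corpora with known ground truth) so the whole
    pipeline is testable without access to proprietary livestock data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
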
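Package: tetragwas
Title: Dosage-Based GWAS and Omics Integration for Autotetraploid Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for dissecting quantitative traits in autotetraploid
    crops such as potato. Provides dosage-aware variant filtering from VCF or
    dosage matrices, a bidirectional windowed linkage-disequilibrium pruning
    algorithm, population-structure utilities (PCA, k-means/BIC cluster
    selection, DAPC-style discriminant analysis, Evanno delta, alignment of
    admixture runs, leave-one-chromosome-out kinship), a mixed-model GWAS with
    eight tetraploid genetic models and six population settings with genomic
    inflation diagnostics, integration of differential-expression results with
    functional-class-scoring enrichment, the HIDECAN layered chromosome
    visualisation, and a synthetic half-sib panel simulator used as the test
    bed for every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    lme4,
    vcfR,
    clue,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
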
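Package: pcaDMR
Title: Principal-Component-Based Detection of Differentially Methylated Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) in Illumina
    EPIC-style methylation array data. Autosomal CpG probes are clustered into
    genic and intergenic candidate regions by genomic distance, per-probe
    M-values are residualized on covariates, and principal components of the
    standardized residuals summarize each region. Regional significance is
    obtained either by meta-analysing per-component association p-values
    (Fisher or Stouffer combination) or by a joint nested-model test, followed
    by Benjamini-Hochberg FDR correction across regions. Includes a
    genome-wide null-simulation framework for estimating false-positive
    rates, power simulations with component-anchored signals, an EPIC-like
    synthetic-data generator, and DMR visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
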
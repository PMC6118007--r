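Package: XiMosaic
Title: Mosaic X-Inactivation Reactivation Simulation and Chromosome-Wide
    Dosage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates mosaic reactivation of the inactive X chromosome (Xi)
    in brain tissue after loss of Xist and re-implements the downstream
    analyses used to detect it in bulk sequencing data. Provides a seeded
    synthetic genome fixture (genes, expression rates, CpG islands,
    methylomes), a per-cell all-or-none Xi reactivation simulator aggregated
    to bulk RNA-seq count matrices, an in-silico methylation-dependent
    restriction digestion (MeD-seq style) simulator with fragment size
    selection and CpG-island counting, and analysis routines: library
    normalization, low-coverage filtering, the Cre+/(Cre+ plus Cre-)
    reactivation-ratio statistic with expression-tercile/quartile
    stratification, X-versus-autosome cumulative fold-change shift tests
    (Wilcoxon rank-sum), binned fold-change shift estimation, CpG-island
    methylation ratio analyses with TSS linkage, and an end-to-end seeded
    pipeline with machine-readable outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
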
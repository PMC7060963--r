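Package: cardiotransit
Title: Calcium-Transient Quantification and Cross-Species Expression
    Concordance for Cardiomyocyte Disease Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying paced calcium transients from confocal
    line-scan recordings of stem-cell-derived cardiomyocytes (amplitude,
    rise time, time to 50% decay, with Savitzky-Golay smoothing and
    robust baseline detection), and for identifying genes with conserved
    expression profiles across human aortic-stenosis and mouse
    pressure-overload heart-failure progression (median-of-ratios
    normalization, per-gene negative-binomial likelihood-ratio tests,
    Benjamini-Hochberg FDR, and ortholog-based concordance filtering).
    Includes calibrated synthetic-data generators for both modalities
    that carry ground truth for parameter-recovery testing, group-level
    statistics (pooled t-tests, one-way random-effects ANOVA over
    differentiation batches, ddCt), and small sequence utilities for
    exon-skip consequence prediction and windowed percent identity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tiff,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
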
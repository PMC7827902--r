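Package: exoref
Title: Selection and Validation of Reference miRNAs for Plasma Exosome qRT-PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify stable endogenous reference microRNAs for
    qRT-PCR normalization of plasma exosomal miRNAs. Implements a
    sequencing-based stability ranking (sample depth and detection
    filters, median-of-ratios count normalization, per-gene batch
    correction, and an abundance-weighted modified Z-score), qRT-PCR
    cycle-threshold validation with Shapiro-Wilk-gated parametric or
    nonparametric group comparisons (unpaired t / Mann-Whitney, one-way
    ANOVA + Tukey HSD / Kruskal-Wallis + Dunn), and delta-delta-Ct
    relative quantification against a chosen reference miRNA. Seeded
    negative-binomial count and Ct-table simulators provide fully
    reproducible synthetic data for calibration and power checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
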
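Package: milkvar
Title: Variance Components and Biological Variability of the Human Milk Lipidome
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end post-processing for targeted human-milk lipidomics
    repeatability studies. Converts raw peak areas into internal-standard
    normalized relative concentrations with isotopologue (M+3) overlap
    correction, applies replicate-CV / signal-to-noise / dilution-linearity
    quality-control filters, imputes left-censored missing values by quantile
    regression on the truncated normal tail (QRILC), fits per-lipid
    random-intercept linear mixed models by profiled restricted maximum
    likelihood to partition between- and within-participant variance, and
    summarises intraclass correlation coefficients, Wald Z and F tests,
    biological coefficients of variation and evening/morning fold changes.
    Ships a synthetic study generator that emulates a 20-subject
    morning/evening milk collection design with known ground-truth variance
    components for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
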
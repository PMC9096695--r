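Package: cnvrisk
Title: Cumulative CNV Risk Scores, Multi-Exposure Association Models, and
    Normative Brain-Deviation Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-individual copy number variant (CNV) risk scores by
    cumulating gene-level dosage-sensitivity and intolerance annotations (pHI,
    pTS, pLI, 1/LOEUF) over deleted or duplicated genes, fits stepwise
    multivariable association models that combine CNV scores with environmental
    stressors and polygenic scores (standardized effects, AIC model comparison,
    Benjamini-Hochberg FDR), and classifies deviation from normative
    brain-volume growth curves via age- and sex-specific centile scores. A
    synthetic-cohort generator reproduces the statistical structure of a large
    community neurodevelopmental sample so the full pipeline is testable
    without access to restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
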
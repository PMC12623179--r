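Package: crossfibro
Title: Cross-Species Dermal Fibroblast Transcriptome Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing bulk RNA-seq responses of dermal fibroblast
    cultures between two rodent species (Peromyscus leucopus and Mus musculus)
    after Toll-like receptor agonist exposure. Implements a housekeeping-gene
    (Gapdh) ratio normalization chain for cross-species expression comparison,
    paired fold-change and t-test differential expression with
    Benjamini-Hochberg correction, species-specificity classification,
    endogenous retrovirus / transposable element length and expression
    analyses (Z-scores, skewness, regression with confidence and prediction
    bands), a six-frame Kozak-context open reading frame scanner, and
    negative-binomial count and ERV sequence simulators that emulate the
    paired study design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
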
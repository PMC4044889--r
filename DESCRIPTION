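Package: panelforge
Title: Multi-Biomarker Panel Discovery for Case/Control Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Panelforge", "Developers", email = "panelforge@example.org",
           role = c("aut", "cre"))
Description: Discovers fixed-size multi-protein biomarker panels from
    case/control plasma proteomics intensity tables. Implements log2
    transformation and quantile normalization, per-protein nested mixed-model
    ANOVA candidate screening, exhaustive enumeration of N-marker panels
    scored by a from-scratch feed-forward neural network trained by
    backpropagation on sum-of-squared errors, and panel selection by
    validation-set ROC AUC under a strict train/validation/test three-way
    data split. Ships a synthetic-data generator that emulates the nested
    variance structure (sample, replicate, residual) of label-free LC-MS/MS
    plasma studies with planted differential proteins, so the whole pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
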
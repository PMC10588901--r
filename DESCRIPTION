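Package: sevcms
Title: Composite Measure Schemes for Evidence-Based Severity Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and evaluates composite measure schemes (CMS) for severity
    assessment of laboratory animals from tabular behavioral and biochemical
    data. Implements the full workflow: data-integrity preselection of
    parameters, Spearman-correlation redundancy pruning, per-parameter ROC/AUC
    discriminatory screening against a binary burden classifier, a resampled
    Box-Cox/PCA procedure that ranks parameters by eigenvector loadings across
    repeated 80/20 training splits, ranked-sum composite severity scores, and
    one-dimensional k-means severity clustering with bootstrap confidence
    borders that assigns individual animals to ordered severity levels.
    Includes a synthetic-data generator with planted group effects for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    pROC,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
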
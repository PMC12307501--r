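Package: ahclock
Title: Proteomic Aging Clocks and Aging-Protein Discovery for Aqueous Humor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for age-resolved aqueous-humor (and other
    body-fluid) proteome matrices: left-censored missing-value imputation,
    per-protein standardization, LOESS expression-trajectory clustering with
    hypergeometric aging-protein enrichment, dual-criterion identification of
    aging proteins (Wilcoxon rank-sum group test intersected with a
    covariate-adjusted linear age model), a stability-selected proteomic age
    clock (repeated cross-validated LASSO feature retention followed by ridge
    regression) with bias-corrected age predictions, delta-age estimation and
    ager stratification, delta-age-adjusted discovery of aging modulators,
    generic GMT over-representation analysis, and a synthetic-cohort
    generator with planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
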
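Package: hillmapr
Title: Coverage-Standardized Plant Diversity Mapping from Citizen-Science
    Records with Regression Kriging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping wild-plant species diversity from biased,
    opportunistic occurrence records such as citizen-science observations.
    Implements incidence-based sample-coverage estimation (Chao-type
    estimators with sample-size doubling), Hill numbers of order 0, 1 and 2
    standardized to a target coverage by rarefaction/extrapolation,
    regression-kriging extrapolation of diversity surfaces (quasi-Poisson
    GLM/GAM trends, residual semivariogram fitting, ordinary kriging) with
    cross-validated model selection, and census-tract disparity analysis via
    spatially correlated linear mixed models. A synthetic-data module
    generates landscapes, communities, biased observer effort and
    SES-attributed tracts with known ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
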
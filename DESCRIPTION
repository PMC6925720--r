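Package: anaemiagamm
Title: Spatial Additive Mixed Models and District Ranking for Childhood Anaemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits generalized additive mixed models for the anaemia status of
    children aged 6-59 months in cluster-sampled household surveys: penalized
    B-spline (P-spline) smooths for nonlinear covariate effects, a
    tensor-product spatial surface over cluster coordinates with a
    four-nearest-neighbour difference penalty, and an i.i.d. district random
    effect, estimated by penalized iteratively weighted least squares with
    REML variance components (empirical Bayes). District performance is
    appraised and ranked from standardized best linear unbiased predictions
    (BLUPs) of the district effects. Includes a seeded synthetic-data
    generator emulating the hierarchical geography and covariate structure of
    DHS/MIS-style surveys so that estimation and ranking can be validated by
    parameter recovery, plus a pipeline that screens covariates, fits the
    model, and exports odds-ratio tables, smooth curves, spatial surfaces and
    district league tables.
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
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
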
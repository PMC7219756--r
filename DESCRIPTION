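Package: fieldgblup
Title: Genomic Prediction for Cereal Field Trials with Single- and
    Multi-Trait GBLUP
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Genomic evaluation of single-seed-descent breeding lines from
    multi-environment yield trials. Builds VanRaden (method 1) genomic
    relationship matrices and pedigree numerator relationship matrices under
    repeated selfing, fits univariate and bivariate GBLUP mixed models with
    combined year-location-trial fixed effects and moving-average spatial
    random effects by average-information REML, estimates plot and line-mean
    heritability and genetic correlations, and evaluates forward
    cross-validated predictive ability of breeding values. Includes a
    synthetic field-trial generator with stored ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
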
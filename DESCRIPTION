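Package: ShiftEnsemble
Title: Chemical-Shift Regression Selection of Weighted Conformational Ensembles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects weighted conformational ensembles of dynamic proteins from
    a candidate structural library by constrained multiple linear regression of
    backbone NMR chemical shifts (1HN, 15NH, 13CA, 13CB). Predicted per-conformer
    shift tables are min-max log-scaled per nucleus, fitted to the experimental
    reference under non-negativity and sum-to-one constraints, sparsified by a
    relative-threshold feature selection, and refit on the selected support.
    Ensembles are validated with per-nucleus and total coefficients of
    determination, secondary-structure proportion statistics, contact-map
    PCA/k-means clustering, iRED N-H order parameters on a fixed-size frame
    expansion, and projection-space chemical-shift errors. A synthetic-data
    layer generates toy conformer ensembles, shift libraries with known convex
    mixtures, and cone-motion N-H vector ensembles for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    pracma,
    bio3d,
    MASS,
    yaml,
    cluster,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'ShiftEnsemble-package.R'
    'ShiftTable-methods.R'
    'constants.R'
    'shift-io.R'
    'scaling.R'
    'regression.R'
    'synthetic.R'
    'structure-io.R'
    'structure-analysis.R'
    'order-parameters.R'
    'validation.R'
    'workflow.R'
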
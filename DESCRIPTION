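Package: gpacc
Title: Outlier Robustness of Heritability and Accuracy Estimation in
    Genomic Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for assessing how single-observation
    outliers in field-trial phenotypes affect heritability and predictive
    accuracy estimation under the RR-BLUP/GBLUP model. Provides a trial
    simulator (doubled-haploid marker panels, alpha-design plot layouts,
    outlier contamination), a REML engine for variance components with
    arbitrary genomic covariance, a two-stage analysis (adjusted means,
    then genomic prediction), five heritability measures, seven predictive
    accuracy estimators, three-fold cross-validation, and paired
    mean-deviation evaluation of estimator robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
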
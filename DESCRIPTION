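Package: bivargp
Title: Bivariate Genomic Prediction with Linear and Convolutional Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and benchmarking toolkit for bivariate genomic
    prediction of correlated quantitative traits with additive, dominance
    and additive-by-additive epistatic architecture. Provides a genotype and
    phenotype simulator calibrated to sow lifetime-productivity traits,
    genotype quality control and imputation, additive/dominance/epistatic
    genomic relationship matrices, a bivariate multi-kernel Gibbs sampler for
    variance components and genetic parameters, bivariate GBLUP, Bayesian
    ridge regression and Bayes A/B marker models, bivariate convolutional and
    locally connected neural-network predictors trained with Adam, Gaussian
    process Bayesian optimization of network hyperparameters with an upper
    confidence bound acquisition, and five-fold cross-validated benchmarking
    by predictive correlation and mean squared error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
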
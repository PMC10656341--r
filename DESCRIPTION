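Package: mlcastep
Title: Stepwise Estimation of Multilevel Latent Class Models with Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits multilevel latent class models for binary items with a
    categorical random effect at the group level and covariates predicting
    low-level class membership. Provides a two-step pseudo-maximum-likelihood
    estimator (measurement model first, structural model second, with
    variance-corrected standard errors that account for first-step
    estimation), alongside the simultaneous one-step and the two-stage
    estimators for benchmarking. Includes upward-downward EM algorithms,
    K-modes-based hierarchical initialization, information criteria and
    entropy-based class-separation measures for class enumeration, and a
    Monte Carlo engine for evaluating bias, efficiency and confidence
    interval coverage of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
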
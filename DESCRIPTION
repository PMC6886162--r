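Package: strsignal
Title: Continuous Probabilistic Modeling of STR Capillary Electrophoresis Signal
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Continuous probabilistic models for short tandem repeat (STR)
    capillary electrophoresis (CE) signal: heteroscedastic Gaussian models
    for allelic, stutter and noise peak heights, Bernoulli drop-out models,
    exponential characterization of DNA degradation from the signal itself
    (decayed amplitude), maximum-likelihood calibration per locus and
    dataset, k-fold cross-validation with one-standard-error model
    selection, a synthetic electropherogram simulator, and a Monte Carlo
    estimator of the posterior probability distribution on the number of
    contributors to a DNA sample.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
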
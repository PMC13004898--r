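Package: gxepref
Title: Gene-by-Environment Analysis of Risk and Time Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how polygenic scores interact with childhood
    environments in shaping economic preferences. Encodes incentivized
    elicitation instruments (ordered-lottery risk tasks and multiple price
    lists for time discounting) and inverts observed choices into
    interval-valued preference parameters; constructs and standardizes
    polygenic scores and ancestry principal components from allele-count
    matrices; fits interval-censored Gaussian, logistic, and
    proportional-odds likelihoods with full group interactions,
    cluster-robust covariance, implied-effect contrasts, and prediction
    profiles; performs sensitivity power analysis by noncentral-F inversion;
    and generates synthetic cohorts with the statistical structure the
    analysis assumes so that every pipeline stage can be validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), MASS, survival, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
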
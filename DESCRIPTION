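Package: hetsim
Title: Monte Carlo Evaluation of Robust Inference for OLS Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for comparing nine inference methods for
    ordinary least squares regression coefficients (classical t-based
    inference, HC3 and HC4 heteroskedasticity-consistent sandwich standard
    errors, and pairs or wild bootstrap combined with bootstrap p-values,
    percentile or bias-corrected and accelerated confidence intervals) under
    factorial violations of the normality and homoskedasticity assumptions.
    Errors are generated by the Fleishman power method with constrained
    resampling on empirical skewness and kurtosis, and error variances follow
    an exponential funnel in a designated predictor. The harness estimates
    type I error, power, confidence-interval coverage and standard-error bias
    over a factorial scenario grid and classifies methods against Bradley's
    stringent and liberal robustness criteria.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    lmtest,
    boot,
    jsonlite
Config/testthat/edition: 3
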
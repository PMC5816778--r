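Package: riskmwtp
Title: Baseline Risk and Marginal Willingness to Pay for Health Risk Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating how marginal willingness to pay (MWTP) for
    morbidity risk reduction varies with perceived baseline risk, built around
    stated-preference purchase decisions for a risk-reducing good priced per
    household. Provides a from-scratch maximum-likelihood bivariate probit for
    latent willingness-to-pay models with correlated parent/child errors,
    including a vectorized bivariate normal CDF, delta-method Wald tests and
    likelihood-ratio machinery; converts normalized coefficients into
    dollar-valued MWTP curves (constant, rectangular hyperbola, step,
    piecewise-linear in baseline risk); integrates MWTP curves into total
    willingness to pay for nonmarginal risk changes; generates synthetic
    survey data with the randomized experimental design and bivariate-normal
    error structure the estimator assumes; and numerically implements the
    two-person expected-utility model of exogenous and endogenous health risk
    that motivates the empirical specifications.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
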
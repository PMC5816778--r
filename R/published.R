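#' Reference estimates from the motivating survey
#'
#' Returns the published bivariate probit coefficient estimates (normalized
#' scale), their standard errors, the risk-bin definitions, and the fixture
#' step/piecewise-linear MWTP curves from the national parent-child
#' stated-preference survey of perceived heart-disease risk (n = 2211) that
#' this package's methods target. The microdata are not public; these printed
#' estimates are the inputs for curve construction, welfare arithmetic and
#' for parameterizing the synthetic-data generator.
#'
#' Structure: `proportionate` and `absolute` hold the base specifications
#' (per-person coefficient lists plus `rho` and the log-likelihood);
#' `interactions` holds the risk-bin interaction specification;
#' `risk_bins` the bin cut points (integer ranges split at half-integers);
#' `step_fixture` / `piecewise_fixture` the published step and
#' piecewise-linear MWTP-vs-risk values treated as fixture curves.
#'
#' @return nested list, parsed from the JSON shipped in `extdata`.
#' @export
published_estimates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "published_estimates.json",
                          package = "riskmwtp")
      if (path == "") path <- file.path("inst", "extdata",
                                        "published_estimates.json")
      cache <<- jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cache
  }
})
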
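# shared fixtures and independent oracles for the suite

# dollar-scale truth implied by the reference proportionate-risk estimates
truth_params <- function() default_wtp_params()

# normalized-scale truth the estimator should recover under truth_params()
truth_normalized <- function() {
  pe <- published_estimates()$proportionate
  c(parent_const = pe$parent[["constant"]], parent_delta = pe$parent[["delta"]],
    parent_q = pe$parent[["price"]], child_const = pe$child[["constant"]],
    child_delta = pe$child[["delta"]], child_q = pe$child[["price"]],
    rho = pe$rho)
}

# pull the normalized estimate vector out of a base-spec fit, truth order
fit_normalized <- function(fit) {
  cf <- coef(fit)
  c(cf[["parent:(Intercept)"]], cf[["parent:delta"]], cf[["parent:q"]],
    cf[["child:(Intercept)"]], cf[["child:delta"]], cf[["child:q"]],
    cf[["rho"]])
}

# a minimal hand-built bvprobit-shaped object for tests of post-fit
# machinery that only reads coefficients/vcov (never the likelihood)
fake_fit <- function(cf, se, spec = "base", on = "delta",
                     bins = default_bins(), rho = 0.9) {
  V <- diag(se^2)
  dimnames(V) <- list(names(cf), names(cf))
  structure(list(coefficients = cf, vcov = V, logLik = -1, n = 1000,
                 df = length(cf), converged = TRUE, grad_norm = 0,
                 rho = rho, spec = spec, on = on, bins = bins,
                 eq_names = c("parent", "child"), boundary = FALSE),
            class = "bvprobit")
}

# brute-force quadrature oracle for the bivariate normal CDF
phi2_oracle <- function(a, b, rho) {
  stats::pnorm(a) * stats::pnorm(b) +
    stats::integrate(function(t) dphi2(a, b, t), 0, rho,
                     rel.tol = 1e-12)$value
}
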
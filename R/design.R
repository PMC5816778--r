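#' Default baseline-risk bins
#'
#' Integer perceived-risk ranges used for the risk-level indicators
#' (parents 0-20, 21-30, 31-46, 47-100; children 0-14, 15-20, 21-30,
#' 31-100), encoded as half-integer cut points so every integer risk falls
#' strictly inside a bin. The highest bin is the omitted reference.
#'
#' @return list with numeric `parent` and `child` cut points.
#' @export
default_bins <- function() {
  list(parent = c(20.5, 30.5, 46.5), child = c(14.5, 20.5, 30.5))
}

bin_labels <- c("lowest", "low", "high", "highest")

# indicator matrix for the three non-reference bins; errors on an empty bin
bin_indicators <- function(r, cuts, person) {
  idx <- findInterval(r, cuts) + 1L  # 1..length(cuts)+1
  counts <- tabulate(idx, nbins = length(cuts) + 1L)
  if (any(counts == 0L))
    stop(sprintf("empty %s risk bin: %s", person,
                 paste(bin_labels[which(counts == 0L)], collapse = ", ")))
  out <- sapply(seq_along(cuts), function(j) as.numeric(idx == j))
  colnames(out) <- paste0("bin_", bin_labels[seq_along(cuts)])
  out
}

ctr <- function(x) x - mean(x)

# interaction of two mean-centered columns, recentered so the invariant
# "every non-constant column has mean zero" holds exactly
ixn <- function(a, b) ctr(ctr(a) * ctr(b))

#' Build mean-centered design matrices for the latent-WTP probit
#'
#' Constructs the parent and child design matrices for the re-parameterized
#' latent willingness-to-pay equation: after subtracting the common price
#' from latent WTP and dividing by the error scale, the estimating equation
#' regresses the purchase indicator on a constant, the mean-centered risk
#' reduction (proportionate `delta` or absolute `omega = delta * R`), and the
#' mean-centered price `q`, whose coefficient identifies `-1/sigma`.
#' Mean-centering uses the estimation sample's own means. All non-constant
#' columns have mean zero to within 1e-10; interaction columns are products
#' of mean-centered parents, recentered.
#'
#' Specifications:
#' \describe{
#'   \item{`base`}{constant, `delta`, `q` (proportionate reduction).}
#'   \item{`absolute`}{constant, `omega`, `q` (absolute reduction,
#'     chances in 100).}
#'   \item{`risk_dummies`}{`base` (or `absolute`) plus three risk-bin
#'     indicators as constant-term shifters only.}
#'   \item{`risk_bins`}{`risk_dummies` plus interactions of the bins with the
#'     risk term and with `q` (12 extra parameters over the two equations;
#'     the restriction that all 12 are zero is the paper-style LR test of
#'     risk-independent MWTP).}
#'   \item{`income`}{`base` plus four income-bracket indicators (highest
#'     omitted) and their interactions with `delta` and `q`.}
#'   \item{`children`}{`base` plus centered number of children and its
#'     interactions with `delta` and `q`.}
#' }
#'
#' @param records household records as from [sim_survey()].
#' @param spec specification name.
#' @param bins list of risk-bin cut points as [default_bins()].
#' @param on for `risk_bins`: interact bins with the proportionate (`delta`)
#'   or absolute (`omega`) risk-reduction term.
#' @return list of class `"wtp_design"`: `parent` and `child`, each holding
#'   design matrix `X` and outcome `y`; plus `spec` and `bins`.
#' @export
build_design <- function(records,
                         spec = c("base", "absolute", "risk_dummies",
                                  "risk_bins", "income", "children"),
                         bins = default_bins(),
                         on = c("delta", "omega")) {
  spec <- match.arg(spec)
  on <- match.arg(on)
  need <- c("delta_p", "delta_k", "price", "r_p", "r_k", "buy_p", "buy_k")
  if (!all(need %in% names(records)))
    stop("records lack required columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  q <- ctr(records$price)

  one_eq <- function(person) {
    delta <- if (person == "parent") records$delta_p else records$delta_k
    r <- if (person == "parent") records$r_p else records$r_k
    risk_raw <- switch(spec,
      absolute = delta * r,
      risk_bins = ,
      risk_dummies = if (on == "omega") delta * r else delta,
      delta)
    risk_name <- if (spec == "absolute" ||
                     (spec %in% c("risk_bins", "risk_dummies") &&
                        on == "omega")) "omega"
                 else "delta"
    X <- cbind(`(Intercept)` = 1, ctr(risk_raw), q = q)
    colnames(X)[2] <- risk_name
    if (spec == "risk_dummies") {
      B <- bin_indicators(r, bins[[person]], person)
      Bc <- apply(B, 2, ctr)
      colnames(Bc) <- colnames(B)
      X <- cbind(X, Bc)
    } else if (spec == "risk_bins") {
      B <- bin_indicators(r, bins[[person]], person)
      Bc <- apply(B, 2, ctr)
      XI <- cbind(Bc,
                  apply(B, 2, function(b) ixn(risk_raw, b)),
                  apply(B, 2, function(b) ixn(records$price, b)))
      colnames(XI) <- c(colnames(B),
                        paste0(risk_name, ":", colnames(B)),
                        paste0("q:", colnames(B)))
      X <- cbind(X, XI)
    } else if (spec == "income") {
      if (!"income_bracket" %in% names(records))
        stop("records lack 'income_bracket'")
      lev <- sort(unique(records$income_bracket))
      ref <- lev[length(lev)]
      B <- sapply(setdiff(lev, ref),
                  function(l) as.numeric(records$income_bracket == l))
      colnames(B) <- paste0("inc_", setdiff(lev, ref))
      XI <- cbind(apply(B, 2, ctr),
                  apply(B, 2, function(b) ixn(risk_raw, b)),
                  apply(B, 2, function(b) ixn(records$price, b)))
      colnames(XI) <- c(colnames(B), paste0("delta:", colnames(B)),
                        paste0("q:", colnames(B)))
      X <- cbind(X, XI)
    } else if (spec == "children") {
      if (!"n_children" %in% names(records))
        stop("records lack 'n_children'")
      nc <- records$n_children
      X <- cbind(X, n_children = ctr(nc),
                 `delta:n_children` = ixn(risk_raw, nc),
                 `q:n_children` = ixn(records$price, nc))
    }
    y <- if (person == "parent") records$buy_p else records$buy_k
    list(X = X, y = y)
  }

  structure(list(parent = one_eq("parent"), child = one_eq("child"),
                 spec = spec, on = on, bins = bins),
            class = "wtp_design")
}

#' Fit a latent-WTP bivariate probit specification
#'
#' Convenience wrapper: [build_design()] then [bvprobit_fit()], with
#' equations labelled `parent` and `child`. The returned fit carries the
#' specification name so downstream curve construction knows which risk term
#' it holds.
#'
#' @inheritParams build_design
#' @param ... passed to [bvprobit_fit()] (e.g. `start`, `tol_grad`).
#' @return a [bvprobit()] fit with extra fields `spec`, `on`, `bins`.
#' @export
fit_wtp <- function(records,
                    spec = c("base", "absolute", "risk_dummies", "risk_bins",
                             "income", "children"),
                    bins = default_bins(), on = c("delta", "omega"), ...) {
  spec <- match.arg(spec)
  on <- match.arg(on)
  d <- build_design(records, spec = spec, bins = bins, on = on)
  fit <- bvprobit_fit(d$parent$X, d$parent$y, d$child$X, d$child$y,
                      eq_names = c("parent", "child"), ...)
  fit$spec <- spec
  fit$on <- d$on
  fit$bins <- bins
  fit$call <- match.call()
  fit
}

#' Serialize a fit to JSON
#'
#' Writes coefficients, standard errors, covariance, log-likelihood, sample
#' size, convergence metadata and the specification name.
#'
#' @param fit a [bvprobit()] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  out <- list(
    spec = if (!is.null(fit$spec)) fit$spec else "custom",
    coefficients = as.list(fit$coefficients),
    se = as.list(stats::setNames(sqrt(pmax(diag(fit$vcov), 0)),
                                 names(fit$coefficients))),
    vcov = unname(fit$vcov),
    logLik = fit$logLik, n = fit$n, rho = fit$rho,
    converged = fit$converged, grad_norm = fit$grad_norm,
    iterations = as.list(fit$iterations))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
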
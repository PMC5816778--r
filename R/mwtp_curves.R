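#' MWTP-versus-baseline-risk curves
#'
#' An `mwtp_curve` maps perceived baseline risk `R` (chances in 100) to the
#' marginal willingness to pay, in dollars per year, for reducing risk by 1
#' chance in 100 at that baseline. Four functional forms are supported:
#'
#' * `constant`: MWTP(R) = m (independent of baseline risk);
#' * `hyperbola`: MWTP(R) = A / R, the rectangular hyperbola implied by a
#'   constant dollar value per *proportionate* reduction (A is the value at
#'   R = 1);
#' * `step`: piecewise-constant levels over risk bins (cut points between
#'   integer risk ranges sit at half-integers);
#' * `piecewise_linear`: continuous, linear between knots.
#'
#' @param m constant MWTP level ($ per 1-in-100 per year).
#' @param A hyperbola scale: MWTP at R = 1.
#' @param cuts increasing interior cut points of the step function.
#' @param levels step levels, `length(cuts) + 1` of them.
#' @param knots,values knot locations and values of the piecewise-linear
#'   form; evaluation is by linear interpolation, constant beyond the
#'   outermost knots.
#' @return an object of class `"mwtp_curve"`.
#' @name mwtp_curve
NULL

new_curve <- function(form, ...) {
  structure(list(form = form, ...), class = "mwtp_curve")
}

#' @rdname mwtp_curve
#' @export
mwtp_constant <- function(m) {
  stopifnot(is.finite(m), m >= 0)
  new_curve("constant", m = m)
}

#' @rdname mwtp_curve
#' @export
mwtp_hyperbola <- function(A) {
  stopifnot(is.finite(A), A >= 0)
  new_curve("hyperbola", A = A)
}

#' @rdname mwtp_curve
#' @export
mwtp_step <- function(cuts, levels) {
  stopifnot(length(levels) == length(cuts) + 1, !is.unsorted(cuts),
            all(levels >= 0))
  new_curve("step", cuts = as.numeric(cuts), levels = as.numeric(levels))
}

#' @rdname mwtp_curve
#' @export
mwtp_piecewise <- function(knots, values) {
  stopifnot(length(knots) == length(values), length(knots) >= 2,
            !is.unsorted(knots))
  new_curve("piecewise_linear", knots = as.numeric(knots),
            values = as.numeric(values))
}

#' Evaluate an MWTP curve
#'
#' @param curve an [mwtp_curve] object.
#' @param R baseline risk(s), chances in 100, in (0, 100].
#' @return MWTP in $ per 1-in-100 reduction per year.
#' @export
mwtp_at <- function(curve, R) {
  stopifnot(inherits(curve, "mwtp_curve"))
  if (any(R <= 0)) stop("baseline risk must be positive")
  switch(curve$form,
    constant = rep(curve$m, length(R)),
    hyperbola = curve$A / R,
    step = curve$levels[findInterval(R, curve$cuts) + 1L],
    piecewise_linear = stats::approx(curve$knots, curve$values, xout = R,
                                     rule = 2)$y)
}

#' @export
predict.mwtp_curve <- function(object, R, ...) mwtp_at(object, R)

#' @export
print.mwtp_curve <- function(x, ...) {
  cat("MWTP curve ($ per 1-in-100 risk reduction per year)\n")
  switch(x$form,
    constant = cat("  constant in baseline risk: m =", x$m, "\n"),
    hyperbola = cat("  rectangular hyperbola: MWTP(R) =", x$A, "/ R\n"),
    step = {
      cat("  step function, cut points:", paste(x$cuts, collapse = ", "), "\n")
      cat("  levels:", paste(x$levels, collapse = ", "), "\n")
    },
    piecewise_linear = {
      cat("  piecewise linear, knots at:",
          paste(x$knots, collapse = ", "), "\n")
      cat("  values:", paste(round(x$values, 4), collapse = ", "), "\n")
    })
  invisible(x)
}

#' Recover dollar-scale WTP slopes from normalized coefficients
#'
#' The price coefficient of the re-parameterized latent-WTP probit equals
#' `-1/sigma`, so dividing any normalized coefficient by the negative of the
#' price coefficient restores the dollar scale. For the proportionate-risk
#' term this yields `gamma` ($ per unit of proportionate reduction); dividing
#' by 100 gives the MWTP for a one-percentage-point reduction.
#'
#' @param coef_risk normalized risk-reduction coefficient (`gamma/sigma`).
#' @param coef_price normalized price coefficient (`-1/sigma`), negative.
#' @return list with `gamma` ($ per unit proportionate reduction) and
#'   `per_point` ($ per percentage point = `gamma/100`).
#' @examples
#' unnormalize(0.9624, -0.0042)$per_point  # 2.29: parents' own risk
#' unnormalize(0.7404, -0.0037)$per_point  # 2.00: children's risk
#' @export
unnormalize <- function(coef_risk, coef_price) {
  if (coef_price >= 0) stop("price coefficient must be negative (-1/sigma)")
  gamma <- coef_risk / (-coef_price)
  list(gamma = gamma, per_point = gamma / 100)
}

#' MWTP per 1-in-100 reduction at a given baseline risk
#'
#' Converts a per-percentage-point MWTP (constant in proportionate terms)
#' into the dollar value of an absolute 1-chance-in-100 reduction at baseline
#' risk `R`: `per_point * 100 / R` — the rectangular-hyperbola evaluation.
#'
#' @param per_point MWTP for a one-percentage-point proportionate reduction.
#' @param R baseline risk, chances in 100, in (0, 100].
#' @return $ per 1-in-100 reduction per year.
#' @examples
#' mwtp_per_chance(2.29, 33.59)  # 6.82 at parents' mean risk
#' mwtp_per_chance(2.00, 24.30)  # 8.23 at children's mean risk
#' @export
mwtp_per_chance <- function(per_point, R) {
  if (any(R <= 0)) stop("baseline risk must be positive")
  if (any(R > 100)) stop("baseline risk is in chances per 100")
  per_point * 100 / R
}

#' Constant MWTP from the absolute-risk specification
#'
#' In the absolute-risk specification the risk term is `omega = delta * R`
#' (chances in 100 eliminated), so its unnormalized coefficient is directly
#' the MWTP for a 1-in-100 reduction, constant in baseline risk.
#'
#' @inheritParams unnormalize
#' @param coef_omega normalized absolute-risk coefficient.
#' @return $ per 1-in-100 reduction per year.
#' @examples
#' absolute_mwtp(0.0227, -0.0042)  # 5.40: parents
#' absolute_mwtp(0.0226, -0.0038)  # 5.95: children
#' @export
absolute_mwtp <- function(coef_omega, coef_price) {
  if (coef_price >= 0) stop("price coefficient must be negative (-1/sigma)")
  coef_omega / (-coef_price)
}

# terms with |z| below the two-sided critical value at `alpha` are pruned
prune_coef <- function(cf, se, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  ifelse(abs(cf / se) >= z, cf, 0)
}

#' Build an MWTP curve from a fitted specification
#'
#' Converts one equation of a fitted latent-WTP bivariate probit into an
#' [mwtp_curve]. Statistically insignificant interaction coefficients (at
#' two-sided level `prune_alpha`) are disregarded before the conversion;
#' pruning never touches the likelihood, only this post-fit construction. If
#' pruning removes the main risk term the curve is undefined and an error is
#' raised.
#'
#' Form/specification pairing: `hyperbola` needs a `delta`-based fit (`base`
#' or `risk_bins` on delta); `constant` needs the `absolute` fit; `step`
#' needs `risk_bins` on `omega`; `piecewise_linear` needs a fit whose risk
#' term interacts `omega` with a linear spline in baseline risk (see
#' [build_design_piecewise()]).
#'
#' @param fit a [fit_wtp()] result.
#' @param person `"parent"` or `"child"`.
#' @param form curve form to construct.
#' @param prune_alpha two-sided significance level for pruning; default 0.05.
#' @return an [mwtp_curve].
#' @export
build_curve <- function(fit, person = c("parent", "child"),
                        form = c("hyperbola", "constant", "step",
                                 "piecewise_linear"),
                        prune_alpha = 0.05) {
  person <- match.arg(person)
  form <- match.arg(form)
  if (!fit$converged) stop("fit did not converge; no curve")
  cf <- fit$coefficients
  se <- sqrt(pmax(diag(fit$vcov), 0))
  pick <- function(term) {
    nm <- paste0(person, ":", term)
    if (!nm %in% names(cf)) stop("fit lacks required term: ", nm)
    c(cf[[nm]], se[[nm]])
  }
  if (form == "hyperbola") {
    risk <- pick("delta"); price <- pick("q")
    if (abs(risk[1] / risk[2]) < stats::qnorm(1 - prune_alpha / 2))
      stop("main risk term pruned: no curve")
    mwtp_hyperbola(unnormalize(risk[1], price[1])$gamma)
  } else if (form == "constant") {
    risk <- pick("omega"); price <- pick("q")
    if (abs(risk[1] / risk[2]) < stats::qnorm(1 - prune_alpha / 2))
      stop("main risk term pruned: no curve")
    mwtp_constant(absolute_mwtp(risk[1], price[1]))
  } else if (form == "step") {
    if (is.null(fit$on) || fit$on != "omega")
      stop("step curve requires a risk_bins fit on the absolute term (omega)")
    risk <- pick("omega"); price <- pick("q")
    if (abs(risk[1] / risk[2]) < stats::qnorm(1 - prune_alpha / 2))
      stop("main risk term pruned: no curve")
    cuts <- fit$bins[[person]]
    labs <- bin_labels[seq_len(length(cuts) + 1L)]
    lev <- vapply(labs, function(lb) {
      if (lb == "highest") {  # omitted reference bin
        dr <- 0; dq <- 0
      } else {
        ri <- pick(paste0("omega:bin_", lb))
        qi <- pick(paste0("q:bin_", lb))
        dr <- prune_coef(ri[1], ri[2], prune_alpha)
        dq <- prune_coef(qi[1], qi[2], prune_alpha)
      }
      absolute_mwtp(risk[1] + dr, price[1] + dq)
    }, numeric(1))
    mwtp_step(cuts, pmax(lev, 0))
  } else {
    # piecewise linear: omega plus omega x (R - k)+ spline terms
    risk <- pick("omega"); price <- pick("q")
    if (abs(risk[1] / risk[2]) < stats::qnorm(1 - prune_alpha / 2))
      stop("main risk term pruned: no curve")
    knots <- fit$bins[[person]]
    slopes <- vapply(seq_along(knots), function(j) {
      tj <- pick(paste0("omega:spline", j))
      prune_coef(tj[1], tj[2], prune_alpha)
    }, numeric(1))
    grid <- sort(unique(c(1, knots, 100)))
    vals <- vapply(grid, function(R) {
      b <- risk[1] + sum(slopes * pmax(R - knots, 0))
      absolute_mwtp(b, price[1])
    }, numeric(1))
    mwtp_piecewise(grid, vals)
  }
}

#' Design matrices for the piecewise-linear-in-risk specification
#'
#' Like [build_design()] with `spec = "absolute"`, but the absolute risk
#' term `omega` additionally interacts with a linear spline in baseline risk
#' with knots at the bin edges, making the implied MWTP a continuous
#' piecewise-linear function of baseline risk.
#'
#' @inheritParams build_design
#' @return a `"wtp_design"` list as in [build_design()].
#' @export
build_design_piecewise <- function(records, bins = default_bins()) {
  need <- c("delta_p", "delta_k", "price", "r_p", "r_k", "buy_p", "buy_k")
  stopifnot(all(need %in% names(records)))
  q <- ctr(records$price)
  one_eq <- function(person) {
    delta <- if (person == "parent") records$delta_p else records$delta_k
    r <- if (person == "parent") records$r_p else records$r_k
    omega <- delta * r
    knots <- bins[[person]]
    S <- sapply(knots, function(k) ixn(omega, pmax(r - k, 0)))
    colnames(S) <- paste0("omega:spline", seq_along(knots))
    X <- cbind(`(Intercept)` = 1, omega = ctr(omega), q = q, S)
    y <- if (person == "parent") records$buy_p else records$buy_k
    list(X = X, y = y)
  }
  structure(list(parent = one_eq("parent"), child = one_eq("child"),
                 spec = "piecewise", on = "omega", bins = bins),
            class = "wtp_design")
}

#' Percent change in MWTP between two baseline risks
#'
#' @param curve an [mwtp_curve].
#' @param R_from,R_to baseline risks in the curve domain.
#' @return percent change `100 * (MWTP(R_to)/MWTP(R_from) - 1)`.
#' @examples
#' # a 40% cut from any baseline raises hyperbola MWTP by 1/0.6 - 1 = 66.7%
#' relative_increase(mwtp_hyperbola(233), 33.59, 0.6 * 33.59)
#' @export
relative_increase <- function(curve, R_from, R_to) {
  from <- mwtp_at(curve, R_from)
  if (from == 0) stop("MWTP at R_from is zero; relative change undefined")
  100 * (mwtp_at(curve, R_to) / from - 1)
}

#' Table of MWTP values by perceived risk level
#'
#' Evaluates a set of curves on a grid of baseline risks, producing the
#' standard report layout (one row per risk level, one column per curve).
#'
#' @param curves named list of [mwtp_curve] objects.
#' @param risks risk grid; default includes the survey mean risks 24.30 and
#'   33.59 alongside round levels.
#' @return data frame.
#' @export
mwtp_grid <- function(curves,
                      risks = c(1, 10, 20, 24.30, 33.59, 50, 75, 100)) {
  stopifnot(length(curves) >= 1, !is.null(names(curves)))
  out <- data.frame(risk = risks)
  for (nm in names(curves)) out[[nm]] <- mwtp_at(curves[[nm]], risks)
  out
}

#' Serialize / deserialize an MWTP curve as JSON
#'
#' @param curve an [mwtp_curve].
#' @param path file path.
#' @return `read_curve` returns the curve; `write_curve` the path, invisibly.
#' @export
write_curve <- function(curve, path) {
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(x$form,
    constant = mwtp_constant(x$m),
    hyperbola = mwtp_hyperbola(x$A),
    step = mwtp_step(x$cuts, x$levels),
    piecewise_linear = mwtp_piecewise(x$knots, x$values),
    stop("unknown curve form: ", x$form))
}
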
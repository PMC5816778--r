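#' State-dependent expected-utility specification
#'
#' A one-period, two-person (parent p, child k), two-health-state model. The
#' parent's utility in joint state `ij` (her own state first; H healthy, S
#' sick) is `U_ij(C) = level_ij + slope_ij * u(C)` with CRRA felicity
#' `u(C) = C^(1-eta)/(1-eta)` (log for `eta = 1`) and consumption `C` equal
#' to the income endowment net of any private risk-reducing spending. The
#' `slope` multipliers control health-state dependence of the marginal
#' utility of consumption — the object that decides whether MWTP rises or
#' falls with baseline risk ("sick anyway" effect); the `level` shifts move
#' utility gaps without touching marginal utility.
#'
#' @param I income endowment ($), positive.
#' @param eta CRRA curvature, `>= 0` (1 gives log utility).
#' @param level,slope named numeric vectors over states `HH, SH, HS, SS`;
#'   slopes must be positive (monotone utility).
#' @return object of class `"utility_spec"`.
#' @export
utility_spec <- function(I, eta = 1,
                         level = c(HH = 0, SH = 0, HS = 0, SS = 0),
                         slope = c(HH = 1, SH = 1, HS = 1, SS = 1)) {
  st <- c("HH", "SH", "HS", "SS")
  stopifnot(I > 0, eta >= 0, all(st %in% names(level)),
            all(st %in% names(slope)))
  if (any(slope[st] <= 0))
    stop("non-monotone utility: all slope multipliers must be positive")
  structure(list(I = I, eta = eta, level = level[st], slope = slope[st]),
            class = "utility_spec")
}

u_felicity <- function(C, eta) {
  if (any(C <= 0)) stop("consumption must be positive on the range used")
  if (eta == 1) log(C) else C^(1 - eta) / (1 - eta)
}

u_felicity_prime <- function(C, eta) C^(-eta)

# U_ij(C) and U'_ij(C) for one joint state
ustate <- function(spec, state, C) {
  spec$level[[state]] + spec$slope[[state]] * u_felicity(C, spec$eta)
}
ustate_prime <- function(spec, state, C) {
  spec$slope[[state]] * u_felicity_prime(C, spec$eta)
}

# expected utility (and marginal utility) of the focal person's H and S
# states, integrating over the other person's risk
eu_parts <- function(spec, C, other_risk, person) {
  if (person == "parent") {
    hs <- c("HH", "HS"); ss <- c("SH", "SS")
  } else {
    hs <- c("HH", "SH"); ss <- c("HS", "SS")
  }
  w <- c(1 - other_risk, other_risk)
  list(
    EU_H = w[1] * ustate(spec, hs[1], C) + w[2] * ustate(spec, hs[2], C),
    EU_S = w[1] * ustate(spec, ss[1], C) + w[2] * ustate(spec, ss[2], C),
    dEU_H = w[1] * ustate_prime(spec, hs[1], C) +
      w[2] * ustate_prime(spec, hs[2], C),
    dEU_S = w[1] * ustate_prime(spec, ss[1], C) +
      w[2] * ustate_prime(spec, ss[2], C))
}

#' MWTP for a marginal risk reduction under exogenous risk
#'
#' The compensating income change per unit reduction in the focal person's
#' morbidity risk at unchanged expected utility:
#' \deqn{MWTP = \frac{EU_H - EU_S}{(1-R)\,EU'_H + R\,EU'_S},}
#' where the H/S split is over the focal person's own state and expectations
#' integrate over the other person's risk. Positive whenever being healthy is
#' preferred; increasing in own baseline risk iff the marginal expected
#' utility of income is larger when healthy ("sick anyway" effect).
#'
#' @param spec a [utility_spec()].
#' @param R_p,R_k morbidity probabilities in (0, 1).
#' @param person whose risk changes, `"parent"` or `"child"`.
#' @param C consumption at evaluation; defaults to the income endowment.
#' @return $ per unit of probability.
#' @export
mwtp_exogenous <- function(spec, R_p, R_k, person = c("parent", "child"),
                           C = spec$I) {
  person <- match.arg(person)
  stopifnot(R_p > 0, R_p < 1, R_k > 0, R_k < 1)
  own <- if (person == "parent") R_p else R_k
  other <- if (person == "parent") R_k else R_p
  p <- eu_parts(spec, C, other, person)
  (p$EU_H - p$EU_S) / ((1 - own) * p$dEU_H + own * p$dEU_S)
}

#' Risk-production technology
#'
#' Morbidity risk as a function of private risk-reducing expenditure `X` and
#' exogenous (e.g. public) risk reduction `G`:
#' `R(X, G) = R0 * exp(-betaX*X - betaG*G - betaXG*X*G)`, or the
#' perfect-substitute variant `R0 * exp(-betaX*(X + phi*G))`. Both are
#' decreasing and convex in `X` (diminishing marginal productivity); the sign
#' of the cross-partial `R^XG` is governed by `betaXG` (or fixed positive in
#' the substitute case).
#'
#' @param R0 baseline risk at `X = G = 0`, in (0, 1).
#' @param betaX,betaG,betaXG effectiveness parameters; `betaX > 0`.
#' @param substitute if `TRUE`, use the perfect-substitute form with
#'   substitution rate `phi`.
#' @param phi substitution rate of `G` for `X` (substitute form only).
#' @return object of class `"risk_tech"`.
#' @export
risk_tech <- function(R0, betaX, betaG = 0, betaXG = 0,
                      substitute = FALSE, phi = 1) {
  stopifnot(R0 > 0, R0 < 1, betaX > 0)
  structure(list(R0 = R0, betaX = betaX, betaG = betaG, betaXG = betaXG,
                 substitute = substitute, phi = phi),
            class = "risk_tech")
}

#' Evaluate a risk technology and its derivatives
#'
#' @param tech a [risk_tech()].
#' @param X private expenditure, `>= 0`.
#' @param G exogenous risk-reduction input.
#' @return list with `R`, `RX`, `RXX`, `RG`, `RXG` (analytic derivatives).
#' @export
tech_eval <- function(tech, X, G) {
  if (tech$substitute) {
    R <- tech$R0 * exp(-tech$betaX * (X + tech$phi * G))
    list(R = R, RX = -tech$betaX * R, RXX = tech$betaX^2 * R,
         RG = -tech$betaX * tech$phi * R,
         RXG = tech$betaX^2 * tech$phi * R)
  } else {
    b <- tech$betaX + tech$betaXG * G
    g <- tech$betaG + tech$betaXG * X
    R <- tech$R0 * exp(-tech$betaX * X - tech$betaG * G -
                         tech$betaXG * X * G)
    list(R = R, RX = -b * R, RXX = b^2 * R, RG = -g * R,
         RXG = R * (b * g - tech$betaXG))
  }
}

#' Optimal private risk-reducing expenditure (endogenous risk)
#'
#' Solves the household's first-order conditions for private expenditures
#' `X_p`, `X_k` that maximize expected utility when each person's morbidity
#' risk is produced by a [risk_tech()] and consumption is income net of total
#' spending. At an interior optimum MWTP for own risk reduction equals the
#' marginal cost `-1/R^X` — utility terms drop out entirely. Solved by
#' bracketed root-finding (Brent) on each FOC with Gauss-Seidel alternation,
#' then Newton-polished to a FOC residual below `tol`.
#'
#' @param spec a [utility_spec()].
#' @param tech_p,tech_k risk technologies for parent and child.
#' @param G exogenous risk-reduction input.
#' @param budget upper bound on total private spending; defaults to
#'   `0.95 * spec$I` (consumption must stay positive).
#' @param tol FOC residual tolerance.
#' @return object of class `"endogenous_solution"`: `X_p`, `X_k`, risks
#'   `R_p`, `R_k`, `MWTP_p`, `MWTP_k` (each `-1/R^X` at the optimum), FOC
#'   residuals, corner flags, expected utility `EU`, and `G`.
#' @export
solve_endogenous <- function(spec, tech_p, tech_k, G, budget = 0.95 * spec$I,
                             tol = 1e-10) {
  stopifnot(budget > 0, budget < spec$I)

  foc <- function(X_own, X_other, tech_own, tech_other, person) {
    C <- spec$I - X_own - X_other
    own <- tech_eval(tech_own, X_own, G)
    oth <- tech_eval(tech_other, X_other, G)
    p <- eu_parts(spec, C, oth$R, person)
    own$RX * (p$EU_S - p$EU_H) -
      ((1 - own$R) * p$dEU_H + own$R * p$dEU_S)
  }
  solve_one <- function(X_other, tech_own, tech_other, person) {
    ub <- budget - X_other
    f0 <- foc(0, X_other, tech_own, tech_other, person)
    if (f0 <= 0) return(list(x = 0, corner = TRUE))   # not worth spending
    fub <- foc(ub, X_other, tech_own, tech_other, person)
    if (fub > 0)
      stop("no interior solution: FOC does not change sign on [0, budget]")
    x <- stats::uniroot(function(x)
      foc(x, X_other, tech_own, tech_other, person),
      c(0, ub), tol = 1e-13)$root
    # Newton polish on the FOC
    for (i in 1:20) {
      fx <- foc(x, X_other, tech_own, tech_other, person)
      if (abs(fx) < tol / 10) break
      h <- 1e-6 * (1 + abs(x))
      d <- (foc(x + h, X_other, tech_own, tech_other, person) -
              foc(x - h, X_other, tech_own, tech_other, person)) / (2 * h)
      x <- min(max(x - fx / d, 0), ub)
    }
    list(x = x, corner = FALSE)
  }

  X_p <- 0; X_k <- 0
  corner_p <- FALSE; corner_k <- FALSE
  for (it in 1:200) {
    sp <- solve_one(X_k, tech_p, tech_k, "parent")
    sk <- solve_one(sp$x, tech_k, tech_p, "child")
    moved <- max(abs(sp$x - X_p), abs(sk$x - X_k))
    X_p <- sp$x; X_k <- sk$x
    corner_p <- sp$corner; corner_k <- sk$corner
    if (moved < 1e-13) break
  }
  ep <- tech_eval(tech_p, X_p, G)
  ek <- tech_eval(tech_k, X_k, G)
  C <- spec$I - X_p - X_k
  pp <- eu_parts(spec, C, ek$R, "parent")
  EU <- (1 - ep$R) * pp$EU_H + ep$R * pp$EU_S
  res_p <- foc(X_p, X_k, tech_p, tech_k, "parent")
  res_k <- foc(X_k, X_p, tech_k, tech_p, "child")
  if (!corner_p && abs(res_p) > tol)
    stop("parent FOC residual above tolerance: ", format(res_p))
  if (!corner_k && abs(res_k) > tol)
    stop("child FOC residual above tolerance: ", format(res_k))
  structure(list(X_p = X_p, X_k = X_k, R_p = ep$R, R_k = ek$R,
                 MWTP_p = -1 / ep$RX, MWTP_k = -1 / ek$RX,
                 foc_p = res_p, foc_k = res_k,
                 corner_p = corner_p, corner_k = corner_k,
                 EU = EU, G = G, I = spec$I),
            class = "endogenous_solution")
}

#' @export
print.endogenous_solution <- function(x, ...) {
  cat("Endogenous-risk optimum (G =", x$G, ")\n")
  cat(sprintf("  X_p* = %.6g%s  R_p = %.6g  MWTP_p* = %.6g\n", x$X_p,
              if (x$corner_p) " (corner)" else "", x$R_p, x$MWTP_p))
  cat(sprintf("  X_k* = %.6g%s  R_k = %.6g  MWTP_k* = %.6g\n", x$X_k,
              if (x$corner_k) " (corner)" else "", x$R_k, x$MWTP_k))
  invisible(x)
}

#' Sensitivity of optimal MWTP to exogenous risk reduction
#'
#' Central finite difference of the parent's optimal MWTP with respect to the
#' exogenous input `G` (identical technologies for parent and child), with
#' the analytic decomposition
#' \deqn{\frac{dMWTP^*}{dG} = \frac{R^{XX}(dX^*/dG) + R^{XG}}{(R^X)^2}}
#' evaluated at the central solution (`dX*/dG` itself by central
#' difference). Because `G` lowers risk, a positive derivative means MWTP
#' falls as baseline risk rises.
#'
#' @param spec a [utility_spec()].
#' @param tech a [risk_tech()] used for both persons.
#' @param G evaluation point.
#' @param h step size.
#' @param budget passed to [solve_endogenous()].
#' @return list with `dMWTP_dG` (finite difference), `analytic`
#'   (decomposition value), `dX_dG`, and `sign`.
#' @export
comparative_statics_dG <- function(spec, tech, G, h = 1e-3,
                                   budget = 0.95 * spec$I) {
  sols <- lapply(c(G - h, G, G + h), function(g)
    solve_endogenous(spec, tech, tech, g, budget = budget))
  if (any(vapply(sols, function(s) s$corner_p, logical(1))))
    stop("corner solution at an evaluation point; derivative undefined")
  dM <- (sols[[3]]$MWTP_p - sols[[1]]$MWTP_p) / (2 * h)
  dX <- (sols[[3]]$X_p - sols[[1]]$X_p) / (2 * h)
  mid <- tech_eval(tech, sols[[2]]$X_p, G)
  analytic <- (mid$RXX * dX + mid$RXG) / mid$RX^2
  list(dMWTP_dG = dM, analytic = analytic, dX_dG = dX, sign = sign(dM))
}

#' Optimality ratio conditions at an endogenous-risk solution
#'
#' At an interior optimum the ratio of the parent's marginal valuations must
#' equal the inverse ratio of marginal products,
#' `MWTP_p*/MWTP_k* = R^X_k / R^X_p`; when unit expenditures buy equal
#' *proportionate* risk reductions (`R^X_i` proportional to `R_i`), this
#' becomes `R_k / R_p`, so per-unit MWTP depends on each person's baseline
#' risk.
#'
#' @param sol an [solve_endogenous()] result.
#' @param tech_p,tech_k the technologies used to produce `sol`.
#' @return list with the MWTP ratio, the marginal-product ratio, the
#'   baseline-risk ratio, and the absolute gap between the first two.
#' @export
ratio_conditions <- function(sol, tech_p, tech_k) {
  ep <- tech_eval(tech_p, sol$X_p, sol$G)
  ek <- tech_eval(tech_k, sol$X_k, sol$G)
  mwtp_ratio <- sol$MWTP_p / sol$MWTP_k
  mp_ratio <- ek$RX / ep$RX
  list(mwtp_ratio = mwtp_ratio, marginal_product_ratio = mp_ratio,
       risk_ratio = ek$R / ep$R, gap = abs(mwtp_ratio - mp_ratio))
}
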
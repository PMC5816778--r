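#' Bivariate probit by maximum likelihood
#'
#' Fits a two-equation probit with correlated standard-normal errors by full
#' maximum likelihood: each binary outcome \eqn{y_j = 1[x_j'\beta_j +
#' \epsilon_j \ge 0]} with \eqn{(\epsilon_1,\epsilon_2)} standard bivariate
#' normal, correlation \eqn{\rho}. The log-likelihood is
#' \deqn{\ell = \sum_i \log \Phi_2(s_{1i} x_{1i}'\beta_1,\; s_{2i}
#' x_{2i}'\beta_2,\; s_{1i} s_{2i}\rho), \qquad s_{ji} = 2 y_{ji} - 1,}
#' maximized over \eqn{(\beta_1, \beta_2, \mathrm{atanh}\,\rho)} with
#' analytic gradients (BFGS followed by Newton polishing until the gradient
#' sup-norm falls below `tol_grad`). Standard errors come from the inverse of
#' a central-finite-difference Hessian at the optimum.
#'
#' This is the estimator used for latent willingness-to-pay models in which a
#' parent states purchase intentions for two risk-reducing goods (one for
#' herself, one for her child) at a shared price, so the two latent
#' willingness-to-pay errors are strongly correlated.
#'
#' @param formula1,formula2 model formulas for the two equations; left-hand
#'   sides must be binary (0/1) vectors.
#' @param data data frame holding all variables.
#' @param start optional numeric start vector `(beta1, beta2, atanh(rho))`;
#'   defaults to per-equation univariate probit fits with `rho = 0`.
#' @param tol_grad convergence requirement on the sup-norm of the score.
#' @param max_newton maximum number of Newton polishing steps.
#' @param eq_names length-2 character, labels for the equations.
#' @return an object of class `"bvprobit"` with components `coefficients`
#'   (named vector; equation-prefixed terms followed by `rho`), `vcov`,
#'   `logLik`, `n`, `converged`, `grad_norm`, `iterations`, `df`, per-equation
#'   index lists, and the matched call. Non-convergence is reported in the
#'   object (and by `print`), never silently.
#' @seealso [lr_test()], [wald_ratio_equality()], [phi2()]
#' @examples
#' set.seed(1)
#' n <- 500
#' x <- rnorm(n)
#' e <- matrix(rnorm(2 * n), n)
#' e[, 2] <- 0.6 * e[, 1] + sqrt(1 - 0.36) * e[, 2]
#' d <- data.frame(x = x,
#'                 y1 = as.integer(0.3 + x + e[, 1] >= 0),
#'                 y2 = as.integer(-0.2 + 0.5 * x + e[, 2] >= 0))
#' fit <- bvprobit(y1 ~ x, y2 ~ x, d)
#' coef(fit)
#' @export
bvprobit <- function(formula1, formula2, data, start = NULL,
                     tol_grad = 1e-6, max_newton = 40L,
                     eq_names = c("eq1", "eq2")) {
  mf1 <- stats::model.frame(formula1, data)
  mf2 <- stats::model.frame(formula2, data)
  X1 <- stats::model.matrix(formula1, mf1)
  X2 <- stats::model.matrix(formula2, mf2)
  y1 <- stats::model.response(mf1)
  y2 <- stats::model.response(mf2)
  fit <- bvprobit_fit(X1, y1, X2, y2, start = start, tol_grad = tol_grad,
                      max_newton = max_newton, eq_names = eq_names)
  fit$call <- match.call()
  fit
}

#' Bivariate probit on explicit design matrices
#'
#' Matrix-interface workhorse behind [bvprobit()]; useful when the two
#' design matrices are built programmatically (see [build_design()]).
#'
#' @param X1,X2 design matrices (including intercept columns as desired).
#' @param y1,y2 binary 0/1 outcome vectors.
#' @inheritParams bvprobit
#' @return see [bvprobit()].
#' @export
bvprobit_fit <- function(X1, y1, X2, y2, start = NULL, tol_grad = 1e-6,
                         max_newton = 40L, eq_names = c("eq1", "eq2")) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  n <- length(y1)
  stopifnot(nrow(X1) == n, nrow(X2) == n, length(y2) == n)
  if (!all(y1 %in% 0:1) || !all(y2 %in% 0:1))
    stop("outcomes must be binary 0/1")
  if (length(unique(y1)) < 2L || length(unique(y2)) < 2L)
    stop("both outcomes must vary")
  if (qr(X1)$rank < ncol(X1) || qr(X2)$rank < ncol(X2))
    stop("design matrix is rank deficient")
  p1 <- ncol(X1); p2 <- ncol(X2)
  s1 <- 2 * y1 - 1; s2 <- 2 * y2 - 1
  s12 <- s1 * s2

  # keep rho strictly inside (-1, 1) even when atanh(rho) wanders far out
  clamp_rho <- function(r) max(min(r, 1 - 1e-10), -1 + 1e-10)

  nll <- function(theta) {
    rho <- clamp_rho(tanh(theta[p1 + p2 + 1]))
    a <- s1 * drop(X1 %*% theta[1:p1])
    b <- s2 * drop(X2 %*% theta[p1 + (1:p2)])
    -sum(log(pmax(phi2(a, b, s12 * rho), 1e-300)))
  }
  ngr <- function(theta) {
    tau <- theta[p1 + p2 + 1]
    rho <- clamp_rho(tanh(tau))
    a <- s1 * drop(X1 %*% theta[1:p1])
    b <- s2 * drop(X2 %*% theta[p1 + (1:p2)])
    r <- s12 * rho
    P <- pmax(phi2(a, b, r), 1e-300)
    om <- sqrt(1 - rho^2)
    ga <- stats::dnorm(a) * stats::pnorm((b - r * a) / om)  # dPhi2/da
    gb <- stats::dnorm(b) * stats::pnorm((a - r * b) / om)  # dPhi2/db
    gr <- dphi2(a, b, r)                                    # dPhi2/drho
    c(-colSums(X1 * (ga * s1 / P)),
      -colSums(X2 * (gb * s2 / P)),
      -sum(gr * s12 / P) * (1 - rho^2))
  }

  if (is.null(start)) {
    # univariate probit starts; separation warnings are harmless here
    b1 <- suppressWarnings(stats::glm.fit(X1, y1,
      family = stats::binomial(link = "probit"))$coefficients)
    b2 <- suppressWarnings(stats::glm.fit(X2, y2,
      family = stats::binomial(link = "probit"))$coefficients)
    start <- c(b1, b2, 0)
  }
  stopifnot(length(start) == p1 + p2 + 1)

  opt <- stats::optim(start, nll, ngr, method = "BFGS",
                      control = list(maxit = 300L, reltol = 1e-14))
  theta <- opt$par
  # Newton polishing with finite-difference Hessian of the score
  iters <- opt$counts[["function"]]
  g <- ngr(theta)
  newton <- 0L
  H <- NULL
  while (max(abs(g)) > tol_grad && newton < max_newton) {
    H <- fd_jacobian(ngr, theta)
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    f0 <- nll(theta)
    lam <- 1
    repeat {
      cand <- theta - lam * step
      if (is.finite(nll(cand)) && nll(cand) <= f0 + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- theta; break }
    }
    theta <- cand
    g <- ngr(theta)
    newton <- newton + 1L
  }
  if (is.null(H) || newton > 0L) {
    H <- fd_jacobian(ngr, theta)
    H <- (H + t(H)) / 2
  }
  grad_norm <- max(abs(g))
  converged <- grad_norm < tol_grad
  rho <- clamp_rho(tanh(theta[p1 + p2 + 1]))

  # vcov on the (beta1, beta2, rho) scale: inverse Hessian, delta for rho
  Vtheta <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, length(theta), length(theta))
  })
  J <- diag(length(theta))
  J[length(theta), length(theta)] <- 1 - rho^2
  V <- J %*% Vtheta %*% t(J)
  V <- (V + t(V)) / 2

  cn1 <- if (!is.null(colnames(X1))) colnames(X1) else paste0("x", 1:p1)
  cn2 <- if (!is.null(colnames(X2))) colnames(X2) else paste0("x", 1:p2)
  nm <- c(paste0(eq_names[1], ":", cn1), paste0(eq_names[2], ":", cn2), "rho")
  cf <- c(theta[1:p1], theta[p1 + (1:p2)], rho)
  names(cf) <- nm
  dimnames(V) <- list(nm, nm)

  structure(list(
    coefficients = cf,
    vcov = V,
    logLik = -nll(theta),
    n = n,
    df = length(theta),
    converged = converged,
    grad_norm = grad_norm,
    iterations = c(bfgs = unname(iters), newton = newton),
    rho = rho,
    eq_names = eq_names,
    idx = list(eq1 = 1:p1, eq2 = p1 + (1:p2), rho = p1 + p2 + 1),
    boundary = abs(rho) > 0.9999,
    call = match.call()
  ), class = "bvprobit")
}

# central finite-difference Jacobian, step 1e-5 * (1 + |theta_j|)
fd_jacobian <- function(fn, theta) {
  p <- length(theta)
  J <- matrix(NA_real_, p, p)
  for (j in 1:p) {
    h <- 1e-5 * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  J
}

#' @export
print.bvprobit <- function(x, ...) {
  cat("Bivariate probit fit (n =", x$n, ")\n")
  cat("log-likelihood:", format(x$logLik, digits = 8),
      " rho:", format(x$rho, digits = 4), "\n")
  if (!x$converged)
    cat("WARNING: not converged (score sup-norm ",
        format(x$grad_norm, digits = 3), ")\n", sep = "")
  if (x$boundary)
    cat("NOTE: rho estimate is at the boundary of the parameter space\n")
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.bvprobit <- function(object, ...) object$coefficients

#' @export
vcov.bvprobit <- function(object, ...) object$vcov

#' @export
logLik.bvprobit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
summary.bvprobit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, logLik = object$logLik, n = object$n,
                 rho = object$rho, converged = object$converged),
            class = "summary.bvprobit")
}

#' @export
print.summary.bvprobit <- function(x, ...) {
  cat("Bivariate probit fit (n =", x$n, ")\n\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("\nlog-likelihood:", format(x$logLik, digits = 8), "\n")
  if (!x$converged) cat("WARNING: not converged\n")
  invisible(x)
}

#' Joint outcome probabilities from a bivariate probit fit
#'
#' @param object a [bvprobit()] fit.
#' @param X1,X2 design matrices at which to predict (defaults require
#'   explicit matrices since the fit does not store its data).
#' @param ... unused.
#' @return matrix with columns `p11, p10, p01, p00, p1., p.1` (joint and
#'   marginal purchase probabilities).
#' @export
predict.bvprobit <- function(object, X1, X2, ...) {
  b1 <- object$coefficients[object$idx$eq1]
  b2 <- object$coefficients[object$idx$eq2]
  rho <- object$rho
  e1 <- drop(as.matrix(X1) %*% b1)
  e2 <- drop(as.matrix(X2) %*% b2)
  p11 <- phi2(e1, e2, rho)
  p1 <- stats::pnorm(e1); p2 <- stats::pnorm(e2)
  cbind(p11 = p11, p10 = p1 - p11, p01 = p2 - p11,
        p00 = 1 - p1 - p2 + p11, `p1.` = p1, `p.1` = p2)
}

#' Likelihood-ratio test of nested bivariate probit fits
#'
#' @param restricted,full [bvprobit()] fits of nested specifications on the
#'   same data.
#' @param tol tolerance on a negative LR statistic before it is treated as an
#'   optimization failure.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(restricted, full, tol = 1e-6) {
  if (restricted$n != full$n)
    stop("fits are not on the same number of observations")
  df <- full$df - restricted$df
  if (df <= 0) stop("'full' must have more free parameters than 'restricted'")
  stat <- 2 * (full$logLik - restricted$logLik)
  if (stat < -tol)
    stop("full-model log-likelihood below restricted model: optimization failure")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Wald test that two WTP ratios are equal
#'
#' Tests \eqn{H_0:\ \gamma_1 = \gamma_2} where each \eqn{\gamma_j =
#' \beta_{risk,j} / (-\beta_{price,j})} is the dollar-valued willingness-to-pay
#' slope recovered from one equation of a bivariate probit fit (the price
#' coefficient identifies \eqn{-1/\sigma_j}). The variance of the difference
#' of ratios uses the delta method on the joint coefficient covariance.
#'
#' @param fit a [bvprobit()] fit.
#' @param terms1,terms2 length-2 character vectors `c(risk, price)` naming the
#'   risk and price coefficients of the two equations (full equation-prefixed
#'   names as in `coef(fit)`).
#' @return list with `statistic` (chi-square, 1 df), `p.value`, `ratio1`,
#'   `ratio2`.
#' @export
wald_ratio_equality <- function(fit, terms1, terms2) {
  cf <- fit$coefficients
  V <- fit$vcov
  nm <- c(terms1, terms2)
  if (!all(nm %in% names(cf))) stop("term names not found in coefficients")
  r1 <- cf[terms1[1]]; q1 <- cf[terms1[2]]
  r2 <- cf[terms2[1]]; q2 <- cf[terms2[2]]
  se_q1 <- sqrt(V[terms1[2], terms1[2]])
  se_q2 <- sqrt(V[terms2[2], terms2[2]])
  if (abs(q1 / se_q1) < 2 || abs(q2 / se_q2) < 2)
    stop("price coefficient indistinguishable from zero: ratio unidentified")
  g1 <- r1 / (-q1); g2 <- r2 / (-q2)
  # d(r/-q)/dr = -1/q ; d(r/-q)/dq = r/q^2
  J <- c(-1 / q1, r1 / q1^2, 1 / q2, -r2 / q2^2)
  Vsub <- V[nm, nm]
  var_diff <- drop(t(J) %*% Vsub %*% J)
  stat <- (g1 - g2)^2 / var_diff
  list(statistic = unname(stat),
       p.value = unname(stats::pchisq(stat, 1, lower.tail = FALSE)),
       ratio1 = unname(g1), ratio2 = unname(g2))
}
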
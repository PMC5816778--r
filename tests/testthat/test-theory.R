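# independent expected-utility oracle used by several tests
eu_oracle <- function(spec, X_p, X_k, R_p, R_k) {
  C <- spec$I - X_p - X_k
  u <- if (spec$eta == 1) log(C) else C^(1 - spec$eta) / (1 - spec$eta)
  U <- spec$level + spec$slope * u  # states HH, SH, HS, SS
  (1 - R_p) * ((1 - R_k) * U[["HH"]] + R_k * U[["HS"]]) +
    R_p * ((1 - R_k) * U[["SH"]] + R_k * U[["SS"]])
}

test_that("exogenous MWTP degenerates correctly", {
  # no utility gap between healthy and sick: MWTP = 0
  us0 <- utility_spec(I = 100, slope = c(HH = 1, SH = 1, HS = 1, SS = 1))
  expect_equal(mwtp_exogenous(us0, 0.3, 0.2, "parent"), 0)
  # state-independent marginal utility: denominator independent of R_p
  us1 <- utility_spec(I = 100, level = c(HH = 2, SH = 0, HS = 2, SS = 0),
                      slope = c(HH = 1, SH = 1, HS = 1, SS = 1))
  vals <- sapply(seq(0.05, 0.9, by = 0.05),
                 function(r) mwtp_exogenous(us1, r, 0.2, "parent"))
  expect_lt(diff(range(vals)), 1e-12)
  expect_error(utility_spec(I = 100, slope = c(HH = -1, SH = 1, HS = 1, SS = 1)),
               "monotone")
})

test_that("exogenous MWTP equals a brute-force compensating variation", {
  # parent utility ln C when healthy, 0.8 ln C when sick; I = 100, R_k = 0.2
  us <- utility_spec(I = 100, eta = 1,
                     slope = c(HH = 1, HS = 1, SH = 0.8, SS = 0.8))
  R_p <- 0.3; R_k <- 0.2
  got <- mwtp_exogenous(us, R_p, R_k, "parent")
  # oracle: income compensation dI holding EU fixed after dR_p = 1e-6
  dR <- 1e-6
  eu0 <- eu_oracle(us, 0, 0, R_p, R_k)
  dI <- uniroot(function(di) {
    sp <- us; sp$I <- 100 + di
    eu_oracle(sp, 0, 0, R_p + dR, R_k) - eu0
  }, c(0, 1), tol = 1e-12)$root
  expect_equal(got, dI / dR, tolerance = 1e-4)
})

test_that("the sick-anyway effect has the predicted direction", {
  grid <- seq(0.05, 0.9, by = 0.05)
  # marginal utility larger when healthy: MWTP strictly increasing in R_p
  us_h <- utility_spec(I = 100, slope = c(HH = 1, HS = 1, SH = 0.7, SS = 0.7))
  v_h <- sapply(grid, function(r) mwtp_exogenous(us_h, r, 0.2, "parent"))
  expect_true(all(diff(v_h) > 0))
  # reversed ordering reverses the slope (keep healthy preferred via levels)
  us_s <- utility_spec(I = 100, level = c(HH = 3, HS = 3, SH = 0, SS = 0),
                       slope = c(HH = 0.7, HS = 0.7, SH = 1, SS = 1))
  v_s <- sapply(grid, function(r) mwtp_exogenous(us_s, r, 0.2, "parent"))
  expect_true(all(diff(v_s) < 0))
})

test_that("endogenous optimum satisfies the marginal-cost identity", {
  us <- utility_spec(I = 100, eta = 1, level = c(HH = 1, SH = 0, HS = 0.7, SS = 0),
                     slope = c(HH = 1, SH = 0.8, HS = 1, SS = 0.8))
  tp <- risk_tech(0.4, betaX = 0.15)
  tk <- risk_tech(0.3, betaX = 0.15)
  sol <- solve_endogenous(us, tp, tk, G = 0)
  expect_false(sol$corner_p || sol$corner_k)
  expect_lt(abs(sol$foc_p), 1e-8)
  expect_lt(abs(sol$foc_k), 1e-8)
  # MWTP* = -1/R^X, and equals the exogenous formula evaluated at the optimum
  ep <- tech_eval(tp, sol$X_p, 0)
  expect_equal(sol$MWTP_p, -1 / ep$RX, tolerance = 1e-6)
  mi <- mwtp_exogenous(us, sol$R_p, sol$R_k, "parent",
                       C = 100 - sol$X_p - sol$X_k)
  expect_equal(mi, sol$MWTP_p, tolerance = 1e-5)
  # second-order: expected utility falls moving off the optimum
  for (eps in c(-0.05, 0.05)) {
    expect_lt(eu_oracle(us, sol$X_p + eps, sol$X_k,
                        tech_eval(tp, sol$X_p + eps, 0)$R, sol$R_k),
              sol$EU)
  }
})

test_that("symmetric households split spending equally", {
  us <- utility_spec(I = 100, slope = c(HH = 1, SH = 0.8, HS = 0.8, SS = 0.66),
                     level = c(HH = 1, SH = 0, HS = 0, SS = -0.8))
  tech <- risk_tech(0.35, betaX = 0.2)
  sol <- solve_endogenous(us, tech, tech, G = 0)
  expect_equal(sol$X_p, sol$X_k, tolerance = 1e-7)
  expect_equal(sol$MWTP_p, sol$MWTP_k, tolerance = 1e-7)
})

test_that("cheaper risk reduction drives optimal risk toward zero", {
  us <- utility_spec(I = 100, slope = c(HH = 1, HS = 1, SH = 0.7, SS = 0.7))
  risks <- spend <- numeric(0)
  for (bx in c(0.1, 0.3, 1, 3)) {
    sol <- solve_endogenous(us, risk_tech(0.4, bx), risk_tech(0.4, bx), G = 0)
    risks <- c(risks, sol$R_p)
    spend <- c(spend, sol$X_p)
    # optimal MWTP stays pinned to the marginal cost at every technology
    expect_equal(sol$MWTP_p, -1 / tech_eval(risk_tech(0.4, bx), sol$X_p, 0)$RX,
                 tolerance = 1e-8)
  }
  expect_true(all(diff(risks) < 0))
  expect_lt(risks[4], 0.01)           # near the lower bound
  expect_true(all(diff(spend) < 0))   # and achieved with less spending
})

test_that("optimal MWTP is invariant to affine rescaling of utilities", {
  us <- utility_spec(I = 100, slope = c(HH = 1, SH = 0.8, HS = 1, SS = 0.8),
                     level = c(HH = 1, SH = 0, HS = 0.7, SS = 0))
  tp <- risk_tech(0.4, 0.15); tk <- risk_tech(0.3, 0.15)
  base <- solve_endogenous(us, tp, tk, G = 0)
  set.seed(5)
  for (i in 1:5) {
    a <- runif(1, -3, 3); b <- runif(1, 0.2, 4)
    us2 <- utility_spec(I = 100, slope = b * us$slope,
                        level = a + b * us$level)
    sol <- solve_endogenous(us2, tp, tk, G = 0)
    expect_equal(sol$MWTP_p, base$MWTP_p, tolerance = 1e-7)
    expect_equal(sol$MWTP_k, base$MWTP_k, tolerance = 1e-7)
  }
})

test_that("corner solutions are reported as corners, not errors", {
  us <- utility_spec(I = 100, slope = c(HH = 1, SH = 0.999, HS = 1, SS = 0.999))
  sol <- solve_endogenous(us, risk_tech(0.05, 0.01), risk_tech(0.05, 0.01),
                          G = 0)
  expect_true(sol$corner_p && sol$corner_k)
  expect_equal(sol$X_p, 0)
})

test_that("MWTP* falls as baseline risk rises when G crowds out X productivity", {
  us <- utility_spec(I = 100, slope = c(HH = 1, HS = 1, SH = 0.8, SS = 0.8))
  tech <- risk_tech(0.4, betaX = 0.15, betaG = 0.05, betaXG = -0.004)
  # check the regime: R^XG > 0 at the optimum
  sol <- solve_endogenous(us, tech, tech, G = 1)
  expect_gt(tech_eval(tech, sol$X_p, 1)$RXG, 0)
  cs <- comparative_statics_dG(us, tech, G = 1, h = 1e-3)
  expect_gt(cs$dMWTP_dG, 0)  # G lowers risk, so MWTP falls with baseline risk
  expect_equal(cs$dMWTP_dG, cs$analytic, tolerance = 1e-3)
})

test_that("perfect-substitute technology is fully offset: dX/dG = -phi", {
  # quasi-linear utility (constant, state-independent marginal utility of
  # consumption): no income effect, so the analytic substitute-case solution
  # z* = X + phi*G is a constant and private spending offsets G exactly
  us <- utility_spec(I = 100, eta = 0,
                     level = c(HH = 1, SH = 0, HS = 0.5, SS = -0.5),
                     slope = c(HH = 0.01, SH = 0.01, HS = 0.01, SS = 0.01))
  tech <- risk_tech(0.4, betaX = 0.2, substitute = TRUE, phi = 0.7)
  cs <- comparative_statics_dG(us, tech, G = 2, h = 1e-3)
  expect_equal(cs$dX_dG, -0.7, tolerance = 1e-6)
  expect_equal(cs$dMWTP_dG, 0, tolerance = 1e-6)  # marginal cost unchanged
})

test_that("central differences converge at second order in the step", {
  us <- utility_spec(I = 100, slope = c(HH = 1, HS = 1, SH = 0.8, SS = 0.8))
  tech <- risk_tech(0.4, betaX = 0.15, betaG = 0.05, betaXG = -0.004)
  d <- sapply(c(0.2, 0.1, 0.05), function(h)
    comparative_statics_dG(us, tech, G = 1, h = h)$dMWTP_dG)
  # successive halvings shrink the error by ~4 (allow a broad band)
  r <- (d[1] - d[2]) / (d[2] - d[3])
  expect_gt(abs(r), 2)
})

test_that("ratio conditions hold at interior optima", {
  us <- utility_spec(I = 100, slope = c(HH = 1, SH = 0.8, HS = 1, SS = 0.8),
                     level = c(HH = 1, SH = 0, HS = 0.7, SS = 0))
  # equal marginal products (symmetric problem): ratio exactly 1
  tech <- risk_tech(0.35, 0.2)
  us_sym <- utility_spec(I = 100,
                         slope = c(HH = 1, SH = 0.8, HS = 0.8, SS = 0.66),
                         level = c(HH = 1, SH = 0, HS = 0, SS = -0.8))
  rsym <- ratio_conditions(solve_endogenous(us_sym, tech, tech, G = 0),
                           tech, tech)
  expect_equal(rsym$mwtp_ratio, 1, tolerance = 1e-7)

  # proportionate technologies (equal betaX): MWTP ratio = risk ratio
  tp <- risk_tech(0.4, 0.15); tk <- risk_tech(0.25, 0.15)
  sol <- solve_endogenous(us, tp, tk, G = 0)
  rc <- ratio_conditions(sol, tp, tk)
  expect_lt(rc$gap, 1e-6)
  expect_equal(rc$mwtp_ratio, rc$risk_ratio, tolerance = 1e-6)

  # state-independent marginal utility with utility-level gaps 0.5 (parent)
  # and 1 (child): equal-betaX FOCs give R_p = 2 R_k at the optimum exactly,
  # so the per-unit MWTP ratio is 1/2
  us_lv <- utility_spec(I = 100,
                        level = c(HH = 1, SH = 0.5, HS = 0, SS = -0.5),
                        slope = c(HH = 1, SH = 1, HS = 1, SS = 1))
  t2 <- risk_tech(0.5, 0.15)
  sol2 <- solve_endogenous(us_lv, t2, t2, G = 0)
  expect_equal(sol2$R_p / sol2$R_k, 2, tolerance = 1e-6)
  rc2 <- ratio_conditions(sol2, t2, t2)
  expect_equal(rc2$mwtp_ratio, 0.5, tolerance = 1e-6)

  # random admissible scenarios: both sides of the optimality ratio agree
  set.seed(8)
  for (i in 1:5) {
    tpr <- risk_tech(runif(1, 0.2, 0.5), runif(1, 0.1, 0.3))
    tkr <- risk_tech(runif(1, 0.1, 0.4), runif(1, 0.1, 0.3))
    rci <- ratio_conditions(solve_endogenous(us, tpr, tkr, G = 0), tpr, tkr)
    expect_lt(rci$gap / rci$mwtp_ratio, 1e-6)
  }
})
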
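---
title: "Baseline risk and the marginal value of health risk reduction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Baseline risk and the marginal value of health risk reduction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskmwtp)
```

# The estimation problem

`riskmwtp` estimates how a parent's marginal willingness to pay (MWTP) for
reductions in heart-disease morbidity risk — her own and her child's —
varies with perceived baseline risk. The data structure is a stated-
preference survey: each household faces one randomly assigned price
$Q \in \{10, 20, 40, 80, 160\}$ dollars per year, a proportionate risk
reduction $\Delta_p \in \{0.1, 0.7\}$ for the parent and
$\Delta_k \in \{0.2, 0.8\}$ for the child (the child's always larger), and
reports two binary purchase intentions. Latent stated willingness to pay is

$$\tilde W_i = \alpha_i + \gamma_i \Delta_i + \sigma_i \varepsilon_i,
\qquad i \in \{p, k\},$$

where $\alpha_i$ absorbs systematic misstatement, $\gamma_i$ is the dollar
value of a unit proportionate reduction, and
$(\varepsilon_p, \varepsilon_k)$ is standard bivariate normal with
correlation $\rho$ — the two decisions share household-level taste shocks,
so $\rho$ is large and positive. Only $1[\tilde W_i \ge Q]$ is observed.
Subtracting $Q$, mean-centering all covariates and dividing by $\sigma_i$
gives a two-equation probit whose price coefficient is $-1/\sigma_i$;
`unnormalize()` divides any coefficient by the negative price coefficient to
restore dollars. Mean-centering uses the estimation sample's own means and
is recomputed per subsample, which also makes all estimates invariant to
location shifts in price (tested).

Functional forms for MWTP per 1-in-100 absolute reduction as a function of
baseline risk $R$ (chances in 100):

* **hyperbola** $A/R$, implied by a constant value per proportionate
  reduction ($A = \gamma$, since an absolute reduction of $\Delta R$ priced
  at $\gamma\Delta$ is worth $\gamma/R$ per unit of $R$);
* **constant**, from re-specifying the risk regressor as the absolute
  reduction $\omega_i = \Delta_i R_i$;
* **step**, from interacting $\omega_i$ and price with baseline-risk bin
  indicators (parents 0–20, 21–30, 31–46, 47–100; children 0–14, 15–20,
  21–30, 31–100; the highest bin is the reference);
* **piecewise-linear**, from interacting $\omega_i$ with a linear spline in
  $R$ with knots at the bin edges (`build_design_piecewise()`).

Following the convention of the reference analysis, interaction coefficients
that are statistically indistinguishable from zero (two-sided level
`prune_alpha`, default 0.05) are disregarded when a curve is built
(`build_curve()`); pruning never enters the likelihood. If pruning removes
the main risk term no curve is produced — that is an error, not a silent
zero curve.

Total willingness to pay for a nonmarginal change from $R_{start}$ down to
$R_{end}$ is the integral of the curve (`total_wtp()`): $m(R_{start}-R_{end})$
for the constant form, $A\ln(R_{start}/R_{end})$ for the hyperbola, exact
piecewise integrals otherwise, each cross-checkable against adaptive
quadrature split at the curve's kinks.

# The likelihood and its numerics

The log-likelihood is
$\ell = \sum_i \log \Phi_2(s_{pi}\, x_{pi}'\beta_p,\; s_{ki}\, x_{ki}'\beta_k,\; s_{pi} s_{ki}\rho)$
with sign flips $s = 2y - 1$. Numerical choices:

* **Bivariate normal CDF** (`phi2()`): vectorized two-branch
  Drezner–Wesolowsky/Genz scheme — 24-point Gauss–Legendre quadrature of the
  single-integral (arcsine) representation for $|\rho| < 0.925$, and the
  transformed tail expansion above. Nodes come from the Golub–Welsch
  eigenvalue construction, cached. Accuracy is ~1e-15 against the closed
  form $\Phi_2(0,0,\rho) = 1/4 + \arcsin(\rho)/2\pi$ and a quadrature
  oracle; the package contract is 1e-7.
* **Parameterization**: $\rho = \tanh(\tau)$ for unconstrained optimization,
  clamped to $\pm(1 - 10^{-10})$ so boundary excursions (e.g. duplicated
  outcomes) degrade gracefully and are flagged (`boundary`), never silent.
* **Optimization**: analytic score (the derivatives of $\Phi_2$ have closed
  forms in $\phi$, $\Phi$ and the bivariate density), BFGS to `reltol`
  1e-14, then Newton polishing with a central-finite-difference Jacobian of
  the score (step $10^{-5}(1+|\theta_j|)$) until the score sup-norm is below
  1e-6; the `converged` flag requires exactly that. Starting values are
  per-equation univariate probits with $\rho = 0$ unless supplied.
* **Standard errors**: inverse observed information from the same
  finite-difference Hessian, with a delta-method transform for $\rho$.
* **Degenerate inputs**: non-varying outcomes and rank-deficient designs are
  errors before any optimization; an empty risk bin errors naming the bin.

`lr_test()` implements the nested likelihood-ratio test (a negative
statistic beyond 1e-6 is reported as an optimization failure rather than
truncated), and `wald_ratio_equality()` the delta-method Wald test that the
dollar-valued slopes $\gamma_p = \gamma_k$; the ratio is refused when the
price coefficient has $|t| < 2$, where it is effectively unidentified.

# What the synthetic generator emulates — and what it does not

`sim_survey()` generates the study conditions: the constrained randomized
design (the child's proportionate reduction always exceeds the parent's, so
$E[\Delta_k] = 0.65$), baseline risks from Beta distributions on $[0, 100]$
moment-matched to the published means/SDs (33.59/20.14 parents, 24.30/15.40
children) and coupled by a Gaussian copula (correlation 0.5 — the reference
analysis reports no parent–child risk correlation, and 0.5 is a realistic
default for within-household risk perceptions; it is a configurable
placeholder), latent WTP per the model above, and the deterministic purchase
rule $\tilde W \ge Q$ (ties buy; measure zero under continuous errors). The
default dollar-scale parameters invert the reference normalized estimates:
$\sigma_i = 1/(-\hat\beta_{q,i})$, $\gamma_i = \widehat{(\gamma/\sigma)}_i
\sigma_i$, and $\alpha_i$ backed out from the normalized constants using the
design means ($\bar Q = 62$, $\bar\Delta_p = 0.4$, $\bar\Delta_k = 0.65$;
for the absolute-risk mode, $\bar\Delta_i \bar R_i$). One master seed spawns
fixed child seeds per stream (design, risks, errors, covariates), so
datasets are byte-for-byte reproducible.

The generator does **not** emulate: the risk-grid elicitation and
initial-to-revised belief updating; real covariate structure (income,
family size and parent gender are independent fillers, so income/family-size
interaction fits on synthetic data estimate true zeros); any correlation
between perceived risk and the disturbance (the real survey's bin-indicator
coefficients may be inconsistent for exactly that reason); or non-normal
taste heterogeneity. Passing tests therefore certify the estimator and the
arithmetic under the model's own assumptions — not that the model is right
for any particular real dataset. The optional `misreport` layer flips a
configurable fraction of positive intentions to "no", emulating the
treatment of uncertain buyers as non-purchasers; it is off by default
because the estimator sees only final indicators.

# The expected-utility module

The theory functions implement the one-period, two-person, two-state model
that motivates the design. Utilities are CRRA with state-dependent level and
slope multipliers, $U_{ij}(C) = \mathrm{level}_{ij} + \mathrm{slope}_{ij}\,
u_\eta(C)$ — the smallest family exhibiting both orderings of the marginal
utility of consumption across health states ($\eta$ is this package's
curvature parameter; $\eta = 1$ is log, $\eta = 0$ quasi-linear). Risk
technologies are exponential, $R(X, G) = R_0 e^{-\beta_X X - \beta_G G -
\beta_{XG} X G}$, plus a perfect-substitute variant $R_0 e^{-\beta_X (X +
\phi G)}$; the family delivers both signs of the cross-partial $R^{XG}$ with
analytic derivatives. With exogenous risk, `mwtp_exogenous()` returns the
compensating income change $\frac{EU_H - EU_S}{(1-R)EU'_H + R\,EU'_S}$; its
slope in own risk is the "sick anyway" effect, positive exactly when
marginal utility is larger in the healthy state. With endogenous risk,
`solve_endogenous()` finds interior optima by bracketed root-finding
(Brent) on each first-order condition with Gauss–Seidel alternation and
Newton polishing to a residual below 1e-10; corners are reported with flags
($X^* = 0$), not errors, except where a derivative is requested at one.
`comparative_statics_dG()` differentiates the optimal MWTP in the exogenous
input $G$ by central differences and verifies the analytic decomposition
$(R^{XX} dX^*/dG + R^{XG})/(R^X)^2$; it reports the sign rather than
assuming it, since the technical condition making the direct effect dominate
is model-specific. A corner matters only for the person whose MWTP is being
differentiated.

Two cautions established while testing, both visible in the test suite: the
"full offset" result for perfect substitutes ($dX^*/dG = -\phi$ exactly)
requires quasi-linear, state-independent marginal utility — with curvature,
the income effect of saved private spending breaks exactness; and "cheap
technology makes optimal MWTP small" is not an implication of the model —
at an interior optimum MWTP equals marginal cost, which stays pinned to the
utility-side value however cheap risk reduction becomes (what vanishes is
the optimal risk level and the spending needed to reach it).

# Design choices made where the design was open

* **Baseline-risk marginal**: Beta on $[0,100]$ — bounded support and
  exactly two free parameters for two published moments; infeasible
  (mean, SD) pairs error out; SD = 0 degenerates to a point mass.
* **Step-curve bin edges at half-integers** (20.5, 30.5, 46.5 / 14.5, 20.5,
  30.5): the published bins are integer ranges, so cutting midway between
  adjacent integers makes membership unambiguous at every integer risk and
  fixes the integration convention for `total_wtp()` on step curves.
* **Interaction columns** are products of mean-centered parents, recentered,
  so the "every non-constant column has mean zero" invariant holds exactly
  (a raw product of centered columns has mean equal to their covariance).
* **Pruning threshold** 0.05 two-sided, matching conventional significance,
  configurable per call.
* **Piecewise-linear estimator** is generic (spline knots at the bin edges);
  the published piecewise values are shipped as a fixture curve for welfare
  comparisons, not used as an estimation target.
* **CLI**: the package's functions, `run_pipeline()` and this vignette are
  the interface; simulate/fit/mwtp/welfare/report stages are orchestrated by
  `run_config()` + `run_pipeline()`, which write CSV/JSON artifacts and a
  seed-stamped run log.

# Problem sizes used by the test suite

Simulation-backed checks are sized to be decisive yet quick: parameter
recovery uses 200 replicates at the survey scale n = 2211 (replicate means
within 2 Monte-Carlo SEs of truth); likelihood-ratio size calibration uses
400 replicates at n = 1000 with 12 restricted degrees of freedom, and the
Wald size calibration 400 replicates at n = 2211, both against a
5% ± 2 percentage-point band; the Monte-Carlo orthant cross-check of the
likelihood uses $10^6$ common-random-number draws per record on a 50-record
dataset with a 3-SE tolerance computed from the achieved Monte-Carlo error.
Consistency is checked as monotone RMSE shrinkage from n = 500 to n = 8000
over 20 replicates each.

# Known limitations

* The estimator assumes bivariate normal errors; no semiparametric or
  random-coefficient alternative is provided, and standard errors are plain
  inverse-Hessian (no clustering or sampling weights).
* Curves are defined on $R \in (0, 100]$ and the package deliberately does
  not extrapolate below $R = 1$ in its reports — the survey design carries
  no information there.
* The hyperbola/constant comparison inherits the rounding of the published
  coefficient tables; quantities derived from them (e.g. the curve scale at
  $R = 1$) can differ from published values in the third significant digit
  because the original analysis used unrounded estimates.
* The endogenous-risk module is one-parent-one-child; multi-child households
  enter only through the family-size regression specification.
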
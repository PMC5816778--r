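{
  "note": "Reference bivariate probit estimates and derived MWTP values, as printed, from the motivating national stated-preference survey of parents' perceived heart-disease risk (n = 2211 parent-child households). Used as fixture inputs for curve construction, welfare arithmetic and simulation truth.",
  "n": 2211,
  "mean_risk": {"parent": 33.59, "child": 24.30},
  "design_means": {"price": 62, "delta_p": 0.4, "delta_k": 0.65},
  "proportionate": {
    "child":     {"constant": -0.3729, "delta": 0.7404, "price": -0.0037},
    "child_se":  {"constant": 0.0277, "delta": 0.0736, "price": 0.0005},
    "parent":    {"constant": -0.4195, "delta": 0.9624, "price": -0.0042},
    "parent_se": {"constant": 0.0281, "delta": 0.0865, "price": 0.0005},
    "rho": 0.8912, "rho_se": 0.0119, "loglik": -2251.86
  },
  "absolute": {
    "child":     {"constant": -0.3725, "omega": 0.0226, "price": -0.0038},
    "child_se":  {"constant": 0.0279, "omega": 0.0022, "price": 0.0005},
    "parent":    {"constant": -0.4196, "omega": 0.0227, "price": -0.0042},
    "parent_se": {"constant": 0.0282, "omega": 0.0019, "price": 0.0005},
    "rho": 0.8833, "rho_se": 0.0120, "loglik": -2235.27
  },
  "interactions": {
    "child": {"constant": -0.3794, "bin_lowest": -0.5244, "bin_low": -0.4311,
      "bin_high": -0.3622, "delta": 0.7500, "price": -0.0037,
      "delta_x_lowest": -0.1214, "delta_x_low": -0.0846, "delta_x_high": -0.1081,
      "price_x_lowest": 0.0017, "price_x_low": -0.000001, "price_x_high": -0.0009},
    "child_se": {"constant": 0.0281, "bin_lowest": 0.0696, "bin_low": 0.0615,
      "bin_high": 0.0635, "delta": 0.0763, "price": 0.0005,
      "delta_x_lowest": 0.2202, "delta_x_low": 0.1955, "delta_x_high": 0.1951,
      "price_x_lowest": 0.0013, "price_x_low": 0.0011, "price_x_high": 0.0012},
    "parent": {"constant": -0.4289, "bin_lowest": -0.4136, "bin_low": -0.3075,
      "bin_high": -0.1059, "delta": 0.9565, "price": -0.0041,
      "delta_x_lowest": 0.2108, "delta_x_low": 0.2787, "delta_x_high": 0.2255,
      "price_x_lowest": 0.0003, "price_x_low": 0.0008, "price_x_high": -0.00006},
    "parent_se": {"constant": 0.0285, "bin_lowest": 0.0639, "bin_low": 0.0584,
      "bin_high": 0.0635, "delta": 0.0894, "price": 0.0006,
      "delta_x_lowest": 0.2414, "delta_x_low": 0.2093, "delta_x_high": 0.2397,
      "price_x_lowest": 0.0013, "price_x_low": 0.0011, "price_x_high": 0.0012},
    "rho": 0.8983, "rho_se": 0.0116, "loglik": -2199.88
  },
  "risk_bins": {
    "parent": {"labels": ["lowest", "low", "high", "highest"],
               "cuts": [20.5, 30.5, 46.5]},
    "child":  {"labels": ["lowest", "low", "high", "highest"],
               "cuts": [14.5, 20.5, 30.5]}
  },
  "step_fixture": {
    "parent": {"cuts": [20.5, 30.5, 46.5], "levels": [14.20, 8.48, 5.58, 2.64]},
    "child":  {"cuts": [14.5, 20.5, 30.5], "levels": [14.07, 10.82, 6.43, 3.95]}
  },
  "piecewise_fixture": {
    "grid": [1, 10, 20, 24.30, 33.59, 50, 75, 100],
    "parent": [27.85, 22.55, 16.65, 14.11, 8.51, 5.01, 3.26, 1.52],
    "child":  [15.02, 12.99, 9.62, 6.25, 5.04, 3.78, 1.86, -0.07]
  }
}
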
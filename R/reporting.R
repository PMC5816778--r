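# one-tail two-proportion z-test (independent samples, pooled variance)
two_prop_z <- function(x1, n1, x2, n2,
                       alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- if (alternative == "greater") stats::pnorm(-z) else stats::pnorm(z)
  list(z = z, p.value = p)
}

#' Purchase-rate tabulation by price and risk reduction
#'
#' Tabulates the proportion of stated purchasers by person (parent/child),
#' proportionate risk-reduction level (low/high) and vaccine price, with
#' one-tail two-proportion z-tests: (a) each price column against the $10
#' column at the same risk level (is demand lower at the higher price?), and
#' (b) high versus low risk reduction at the same price (is demand higher
#' when the vaccine does more?).
#'
#' @param records household records as from [sim_survey()].
#' @return data frame with one row per (person, delta level, price) cell:
#'   `n`, `prop`, `z_vs_10`/`p_vs_10` (price comparison, NA in the $10
#'   column) and `z_delta`/`p_delta` (high-vs-low comparison, reported on
#'   the high-delta rows). Empty cells yield NA with a warning.
#' @export
tabulate_purchase_rates <- function(records) {
  prices <- sort(unique(records$price))
  out <- list()
  for (person in c("parent", "child")) {
    dcol <- if (person == "parent") "delta_p" else "delta_k"
    bcol <- if (person == "parent") "buy_p" else "buy_k"
    dlev <- sort(unique(records[[dcol]]))
    for (dl in dlev) {
      for (pr in prices) {
        sel <- records[[dcol]] == dl & records$price == pr
        n <- sum(sel)
        if (n < 2) {
          warning(sprintf("cell %s delta=%g price=%g has <2 records",
                          person, dl, pr))
          row <- data.frame(person = person, delta = dl, price = pr,
                            n = n, prop = NA_real_, z_vs_10 = NA_real_,
                            p_vs_10 = NA_real_, z_delta = NA_real_,
                            p_delta = NA_real_)
          out[[length(out) + 1]] <- row
          next
        }
        x <- sum(records[[bcol]][sel])
        z10 <- p10 <- NA_real_
        if (pr != prices[1]) {
          ref <- records[[dcol]] == dl & records$price == prices[1]
          if (sum(ref) >= 2) {
            t1 <- two_prop_z(sum(records[[bcol]][ref]), sum(ref), x, n,
                             alternative = "greater")
            z10 <- t1$z; p10 <- t1$p.value
          }
        }
        zd <- pd <- NA_real_
        if (dl == max(dlev)) {
          lo <- records[[dcol]] == min(dlev) & records$price == pr
          if (sum(lo) >= 2) {
            t2 <- two_prop_z(x, n, sum(records[[bcol]][lo]), sum(lo),
                             alternative = "greater")
            zd <- t2$z; pd <- t2$p.value
          }
        }
        out[[length(out) + 1]] <- data.frame(
          person = person, delta = dl, price = pr, n = n, prop = x / n,
          z_vs_10 = z10, p_vs_10 = p10, z_delta = zd, p_delta = pd)
      }
    }
  }
  do.call(rbind, out)
}

#' Run configuration for the full pipeline
#'
#' @param n number of households.
#' @param seed master seed.
#' @param params a [wtp_params()] object.
#' @param parent_moments,child_moments baseline-risk moment targets.
#' @param risk_cor copula correlation of the two risks.
#' @param specs specifications to fit (subset of those in [build_design()]).
#' @param bins risk-bin cut points.
#' @param prune_alpha pruning level for curve construction.
#' @param misreport positive-intention flip fraction.
#' @param welfare_from,welfare_to risk change for the welfare illustration.
#' @param outdir output directory.
#' @return validated config list of class `"run_config"`.
#' @export
run_config <- function(n = 2211, seed = 1, params = default_wtp_params(),
                       parent_moments = c(33.59, 20.14),
                       child_moments = c(24.30, 15.40), risk_cor = 0.5,
                       specs = c("base", "absolute"),
                       bins = default_bins(), prune_alpha = 0.05,
                       misreport = 0, welfare_from = 33.59, welfare_to = 20,
                       outdir = tempfile("riskmwtp_run_")) {
  if (n < 1) stop("config invalid: n must be >= 1")
  stopifnot(inherits(params, "wtp_params"),
            all(specs %in% c("base", "absolute", "risk_dummies", "risk_bins",
                             "income", "children")),
            prune_alpha > 0, prune_alpha < 1,
            welfare_to < welfare_from, welfare_to > 0, welfare_from <= 100)
  structure(list(n = n, seed = as.integer(seed), params = params,
                 parent_moments = parent_moments,
                 child_moments = child_moments, risk_cor = risk_cor,
                 specs = specs, bins = bins, prune_alpha = prune_alpha,
                 misreport = misreport, welfare_from = welfare_from,
                 welfare_to = welfare_to, outdir = outdir),
            class = "run_config")
}

#' Simulate, fit, tabulate, build curves, and integrate welfare
#'
#' End-to-end orchestration: generates a synthetic survey under the config,
#' fits each requested specification, writes the dataset CSV, one fit JSON
#' per specification, the purchase-rate table, an MWTP-by-risk grid and the
#' welfare comparison, plus a run log recording seeds. Identical configs give
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return list with the records, fits, curves, purchase table, MWTP grid,
#'   welfare comparison, and output paths; invisibly writes files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  records <- stage("simulate",
    sim_survey(config$n, config$seed, config$params,
               config$parent_moments, config$child_moments,
               config$risk_cor, misreport = config$misreport))
  paths <- list(dataset = file.path(config$outdir, "dataset.csv"))
  write_survey(records, paths$dataset)

  fits <- list()
  for (sp in config$specs) {
    fits[[sp]] <- stage(paste0("fit:", sp),
      fit_wtp(records, spec = sp, bins = config$bins))
    paths[[paste0("fit_", sp)]] <-
      file.path(config$outdir, paste0("fit_", sp, ".json"))
    write_fit(fits[[sp]], paths[[paste0("fit_", sp)]])
  }

  rates <- stage("tabulate", tabulate_purchase_rates(records))
  paths$rates <- file.path(config$outdir, "purchase_rates.csv")
  utils::write.csv(rates, paths$rates, row.names = FALSE)

  curves <- list()
  if ("base" %in% config$specs)
    curves$parent_hyperbola <- stage("curves",
      build_curve(fits$base, "parent", "hyperbola", config$prune_alpha))
  if ("absolute" %in% config$specs)
    curves$parent_constant <- stage("curves",
      build_curve(fits$absolute, "parent", "constant", config$prune_alpha))

  grid <- welfare <- NULL
  if (length(curves) >= 1) {
    grid <- mwtp_grid(curves)
    paths$grid <- file.path(config$outdir, "mwtp_grid.csv")
    utils::write.csv(grid, paths$grid, row.names = FALSE)
  }
  if (length(curves) >= 2) {
    welfare <- stage("welfare",
      compare_forms(curves, config$welfare_from, config$welfare_to))
    paths$welfare <- file.path(config$outdir, "welfare.csv")
    utils::write.csv(
      data.frame(curve = names(welfare$total), total_wtp = welfare$total),
      paths$welfare, row.names = FALSE)
  }

  log_lines <- c(
    paste("master seed:", config$seed),
    paste("child stream seeds (design/risks/errors/covariates):",
          paste(config$seed + 0:3, collapse = ", ")),
    paste("n:", config$n),
    paste("specs:", paste(config$specs, collapse = ", ")))
  paths$log <- file.path(config$outdir, "run_log.txt")
  writeLines(log_lines, paths$log)

  invisible(list(records = records, fits = fits, curves = curves,
                 purchase_rates = rates, mwtp_grid = grid,
                 welfare = welfare, paths = paths))
}
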
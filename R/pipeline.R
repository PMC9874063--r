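#' Run the full model-comparison pipeline
#'
#' End-to-end workflow: diagnostics (VIF, Kolmogorov-Smirnov Poisson fit,
#' dispersion ratio, Breusch-Pagan heterogeneity), global Poisson fit,
#' global generalized Poisson fit, leave-one-out CV bandwidth search over
#' the requested kernels, GWGPR with the CV-best kernel, simultaneous and
#' partial tests, significance grouping, and an AIC comparison across the
#' three models (ascending AIC; the best model is named explicitly).
#'
#' @param ds a \code{\link{spatial_count_dataset}}, or the name of a
#'   built-in \code{\link{preset}} (its dataset is generated at the preset
#'   seed).
#' @param alpha significance level used in every test.
#' @param kernels character vector of kernel kinds to compare.
#' @param phi_mode dispersion mode for GPR and the local fits.
#' @param verbose print one line per completed stage.
#' @return Object of class \code{gwgpr_report}: \code{diagnostics},
#'   \code{poisson}, \code{gpr}, \code{bandwidth} (list of search results
#'   per kernel), \code{best_kernel}, \code{gwgpr}, \code{tests},
#'   \code{groups}, \code{aic_table} (ascending), \code{best_model}.
#' @export
run_pipeline <- function(ds, alpha = 0.05,
                         kernels = c("fixed_bisquare", "fixed_tricube",
                                     "adaptive_bisquare"),
                         phi_mode = "moments", verbose = FALSE) {
  if (is.character(ds)) ds <- generate_scenario(preset(ds))$dataset
  stopifnot(inherits(ds, "spatial_count_dataset"))
  say <- function(...) if (verbose) message(sprintf(...))

  diagnostics <- diagnose(ds, alpha = alpha)
  say("diagnostics done (BP p = %.4g)", diagnostics$bp$p.value)
  pois <- diagnostics$poisson_fit
  gpr <- fit_gpr(ds, phi_mode = phi_mode)
  say("global GPR done (phi = %.4f)", gpr$phi)

  dm <- distance_matrix(ds)
  searches <- lapply(kernels, function(kk) {
    r <- select_bandwidth(ds, kind = kk, phi_mode = phi_mode, dm = dm,
                          beta_init = pois$coefficients)
    say("bandwidth search %s: optimum %.5g, CV %.5g", kk, r$bandwidth, r$cv)
    r
  })
  names(searches) <- kernels
  cvs <- vapply(searches, `[[`, numeric(1), "cv")
  best_kernel <- kernels[which.min(cvs)]
  gw <- fit_gwgpr(ds, searches[[best_kernel]]$spec, phi_mode = phi_mode,
                  alpha = alpha)
  say("GWGPR done (AIC %.4f)", gw$aic)

  tests <- list(poisson_deviance = deviance_test(pois, alpha),
                poisson_wald = wald_tests(pois, alpha),
                gpr_mlrt = gpr_mlrt(gpr, alpha = alpha),
                gpr_wald = gpr_wald(gpr, alpha),
                gwgpr_simultaneous = gwgpr_simultaneous_test(gw, alpha = alpha),
                gwgpr_partial = gw$partial)
  aic_table <- data.frame(
    model = c("Poisson", "GPR", "GWGPR"),
    deviance = c(pois$deviance, gpr$deviance, gw$deviance),
    aic = c(pois$aic, gpr$aic, gw$aic),
    stringsAsFactors = FALSE)
  aic_table <- aic_table[order(aic_table$aic), ]
  rownames(aic_table) <- NULL
  structure(list(diagnostics = diagnostics, poisson = pois, gpr = gpr,
                 bandwidth = searches, best_kernel = best_kernel,
                 gwgpr = gw, tests = tests, groups = gw$groups,
                 aic_table = aic_table, best_model = aic_table$model[1],
                 alpha = alpha),
            class = "gwgpr_report")
}

#' @export
print.gwgpr_report <- function(x, ...) {
  print(x$diagnostics)
  cat("\n== Kernel comparison (leave-one-out CV) ==\n")
  cmp <- data.frame(kernel = names(x$bandwidth),
                    bandwidth = vapply(x$bandwidth, `[[`, numeric(1), "bandwidth"),
                    cv = vapply(x$bandwidth, `[[`, numeric(1), "cv"))
  print(cmp, row.names = FALSE)
  cat("Selected kernel:", x$best_kernel, "\n")
  cat("\n== Global Poisson ==\n"); print(x$poisson)
  cat("\n== Global GPR ==\n"); print(x$gpr)
  cat("\n== GWGPR ==\n"); print(x$gwgpr)
  cat("\n== Significance groups ==\n"); print(x$groups)
  cat("\n== Model comparison (ascending AIC) ==\n")
  print(x$aic_table, row.names = FALSE)
  cat("Best model:", x$best_model, "\n")
  if (!x$diagnostics$bp$reject)
    cat("Note: BP test did not reject homogeneity; spatial modelling not indicated.\n")
  invisible(x)
}

#' Flatten a pipeline report to plain lists for JSON export
#'
#' Timestamps and environment details are deliberately absent, so the same
#' data and seed give byte-identical serialised output.
#'
#' @param report a \code{gwgpr_report}.
#' @return Nested list of plain vectors/data frames.
#' @export
report_as_list <- function(report) {
  stopifnot(inherits(report, "gwgpr_report"))
  list(
    diagnostics = list(
      vif = if (is.null(report$diagnostics$vif)) NULL else
        as.list(report$diagnostics$vif),
      ks = report$diagnostics$ks[c("statistic", "mean", "p.value", "reject")],
      dispersion = report$diagnostics$dispersion[c("statistic", "df", "ratio", "classification")],
      bp = report$diagnostics$bp[c("statistic", "df", "p.value", "reject")]),
    kernels = lapply(report$bandwidth, function(b) list(bandwidth = b$bandwidth, cv = b$cv)),
    best_kernel = report$best_kernel,
    poisson = list(coefficients = as.list(report$poisson$coefficients),
                   deviance = report$poisson$deviance, aic = report$poisson$aic),
    gpr = list(coefficients = as.list(report$gpr$coefficients),
               phi = report$gpr$phi, deviance = report$gpr$deviance,
               aic = report$gpr$aic),
    gwgpr = list(deviance = report$gwgpr$deviance, aic = report$gwgpr$aic,
                 phi_range = range(report$gwgpr$phi),
                 n_groups = length(report$groups)),
    aic_table = report$aic_table,
    best_model = report$best_model)
}
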
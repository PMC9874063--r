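#' Kernel-weighted local generalized Poisson log-likelihood
#'
#' The local log-likelihood at a regression point is the sum of
#' per-observation generalized Poisson log-density terms, each multiplied by
#' its geographic kernel weight:
#' \code{sum_j w_j * gp_logpmf(y_j, exp(x_j' beta), phi)} over the
#' positively weighted observations. With unit weights this reduces to the
#' global GPR log-likelihood; a one-hot weight row reduces to a single
#' observation's log-density.
#'
#' @param beta local coefficient vector, length k + 1 (intercept first).
#' @param phi local dispersion.
#' @param ds a \code{\link{spatial_count_dataset}}.
#' @param w_row weight vector of length n with entries in [0, 1].
#' @return Scalar weighted log-likelihood.
#' @export
local_loglik <- function(beta, phi, ds, w_row) {
  stopifnot(inherits(ds, "spatial_count_dataset"))
  if (length(w_row) != ds$n) stop("local_loglik: w_row must have length n")
  if (any(w_row < 0 | w_row > 1)) stop("local_loglik: weights must lie in [0, 1]")
  A <- cbind(1, ds$X)
  ll <- gp_wloglik(ds$y, A, beta, phi, w_row)
  if (!is.finite(ll))
    stop("local_loglik: support constraint violated at a positively weighted observation")
  ll
}

#' Fit the local model at one regression point
#'
#' Weighted generalized Poisson maximum likelihood using the kernel weights
#' of a single row: Newton-Raphson for the local coefficients (with
#' step-halving and a 1e-8 ridge retry on a singular Hessian) alternated
#' with local dispersion updates (weighted moments by default, profile
#' Newton otherwise). Standard errors come from the inverse observed
#' information of the weighted log-likelihood.
#'
#' @param ds a \code{\link{spatial_count_dataset}}.
#' @param w_row weights for this regression point (length n, >= k + 2
#'   strictly positive entries).
#' @param location optional index i of the regression point; when given,
#'   the fitted own-location mean \code{mu_i = exp(x_i' beta)} is filled in.
#' @param beta_init,phi_init optional starting values.
#' @param phi_mode \code{"moments"} or \code{"newton"}; \code{"fixed"}
#'   keeps \code{phi_init} (used by the global-phi variant).
#' @param tol,max_iter convergence control.
#' @return Object of class \code{local_fit}: \code{location},
#'   \code{coefficients}, \code{phi}, \code{se}, \code{z}, \code{mu_i},
#'   \code{loglik}, \code{converged}, \code{n_iter}.
#' @export
fit_local <- function(ds, w_row, location = NULL, beta_init = NULL,
                      phi_init = 0, phi_mode = c("moments", "newton", "fixed"),
                      tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(ds, "spatial_count_dataset"))
  phi_mode <- match.arg(phi_mode)
  if (length(w_row) != ds$n) stop("fit_local: w_row must have length n")
  if (sum(w_row > 0) < ds$k + 2L)
    stop(sprintf("fit_local: only %d positively weighted observation(s); need >= k + 2 = %d%s",
                 sum(w_row > 0), ds$k + 2L,
                 if (is.null(location)) "" else sprintf(" (location %d)", location)))
  A <- cbind("(Intercept)" = 1, ds$X)
  eng <- gpr_engine(ds$y, A, w = w_row,
                    phi_mode = if (phi_mode == "fixed") "moments" else phi_mode,
                    beta_init = beta_init, phi_init = phi_init,
                    est_phi = phi_mode != "fixed",
                    tol = tol, max_iter = max_iter)
  mu_i <- if (is.null(location)) NA_real_ else
    exp(drop(A[location, , drop = FALSE] %*% eng$beta))
  z <- ifelse(eng$se > 0 & is.finite(eng$se), eng$beta / eng$se, NA_real_)
  structure(list(location = location,
                 coefficients = stats::setNames(eng$beta, colnames(A)),
                 phi = eng$phi,
                 se = stats::setNames(eng$se, colnames(A)),
                 se_phi = eng$se_phi,
                 z = stats::setNames(z, colnames(A)),
                 mu_i = mu_i, loglik = eng$loglik,
                 converged = eng$converged, n_iter = eng$n_iter),
            class = "local_fit")
}

#' Fit a geographically weighted generalized Poisson regression
#'
#' Runs \code{\link{fit_local}} at every observation location with that
#' location's weight-matrix row (self-weight 1), then assembles model-level
#' summaries: the plug-in log-likelihood
#' \code{lnL = sum_i gp_logpmf(y_i, mu_i, phi_i)} where each observation is
#' evaluated under its own local fit, the deviance against the global
#' intercept-only GPR, the AIC \code{-2 lnL + 2 (k + 2)}, per-location Wald
#' tests at level \code{alpha}, significant-variable sets, and the
#' partition of locations into groups sharing an identical significant set.
#'
#' Local p-values are not multiplicity-adjusted.
#'
#' @param ds a \code{\link{spatial_count_dataset}}.
#' @param spec a \code{\link{kernel_spec}} (e.g. from
#'   \code{\link{select_bandwidth}}).
#' @param phi_mode local dispersion mode: \code{"moments"} (default) or
#'   \code{"newton"}.
#' @param global_phi if TRUE, the global GPR dispersion estimate is reused
#'   at every location instead of local dispersion.
#' @param alpha significance level for the partial tests.
#' @param tol,max_iter convergence control for the local fits.
#' @return Object of class \code{gwgpr_fit}: \code{local} (list of n
#'   \code{local_fit}, input order), \code{beta} and \code{z} (n x (k+1)
#'   matrices), \code{phi} (length n), \code{fitted}, \code{loglik},
#'   \code{loglik_null}, \code{deviance}, \code{aic}, \code{partial}
#'   (long-format test table), \code{significant_sets}, \code{groups},
#'   \code{spec}, \code{global_gpr}.
#' @export
fit_gwgpr <- function(ds, spec, phi_mode = c("moments", "newton"),
                      global_phi = FALSE, alpha = 0.05,
                      tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(ds, "spatial_count_dataset"), inherits(spec, "kernel_spec"))
  phi_mode <- match.arg(phi_mode)
  dm <- distance_matrix(ds)
  W <- weight_matrix(dm, spec, min_positive = ds$k + 2L)
  gfit <- fit_gpr(ds, phi_mode = phi_mode, tol = tol, max_iter = max_iter)
  A <- cbind(1, ds$X)
  locals <- vector("list", ds$n)
  for (i in seq_len(ds$n)) {
    locals[[i]] <- tryCatch(
      fit_local(ds, W$w[i, ], location = i,
                beta_init = gfit$coefficients,
                phi_init = if (global_phi) gfit$phi else 0,
                phi_mode = if (global_phi) "fixed" else phi_mode,
                tol = tol, max_iter = max_iter),
      error = function(e)
        stop(sprintf("fit_gwgpr: local fit failed at location %d (%s): %s",
                     i, ds$location_labels[i], conditionMessage(e)),
             call. = FALSE))
  }
  beta_mat <- t(vapply(locals, `[[`, numeric(ds$k + 1L), "coefficients"))
  z_mat <- t(vapply(locals, `[[`, numeric(ds$k + 1L), "z"))
  se_mat <- t(vapply(locals, `[[`, numeric(ds$k + 1L), "se"))
  phi_vec <- vapply(locals, `[[`, numeric(1), "phi")
  mu_vec <- vapply(locals, `[[`, numeric(1), "mu_i")
  colnames(beta_mat) <- colnames(z_mat) <- colnames(se_mat) <-
    c("(Intercept)", ds$predictor_names)
  ll <- sum(gp_logpmf_safe(ds$y, mu_vec, phi_vec))
  fit <- structure(list(local = locals, beta = beta_mat, z = z_mat,
                        se = se_mat, phi = phi_vec, fitted = mu_vec,
                        loglik = ll, loglik_null = gfit$loglik_null,
                        deviance = max(0, -2 * (gfit$loglik_null - ll)),
                        aic = -2 * ll + 2 * (ds$k + 2L),
                        spec = spec, global_gpr = gfit, alpha = alpha,
                        n = ds$n, k = ds$k,
                        predictor_names = ds$predictor_names,
                        location_labels = ds$location_labels,
                        converged = vapply(locals, `[[`, logical(1), "converged")),
                   class = "gwgpr_fit")
  fit$partial <- gwgpr_partial_tests(fit, alpha = alpha)
  fit$significant_sets <- significant_sets_from_partial(fit$partial, ds)
  fit$groups <- significance_groups(fit)
  fit
}

# elementwise gp log-density with per-observation phi
gp_logpmf_safe <- function(y, mu, phi) {
  mapply(function(yi, mi, pi) gp_logpmf(yi, mi, pi), y, mu, phi)
}

#' @export
print.gwgpr_fit <- function(x, ...) {
  cat("Geographically weighted generalized Poisson regression\n")
  print(x$spec)
  cat(sprintf("n = %d locations, k = %d predictors; %d/%d local fits converged\n",
              x$n, x$k, sum(x$converged), x$n))
  cat("Local coefficient summaries (min / median / max):\n")
  qs <- apply(x$beta, 2, stats::quantile, probs = c(0, 0.5, 1))
  print(round(t(qs), 5))
  cat(sprintf("phi range: [%.4f, %.4f]\n", min(x$phi), max(x$phi)))
  cat(sprintf("Deviance: %.4f   logLik: %.4f   AIC: %.4f\n",
              x$deviance, x$loglik, x$aic))
  cat(sprintf("%d significance group(s) at alpha = %g\n",
              length(x$groups), x$alpha))
  invisible(x)
}

#' Simultaneous test for a GWGPR fit
#'
#' \code{D = -2 (lnL_null - lnL_gwgpr)} where the null is the global
#' intercept-only generalized Poisson model and the GWGPR log-likelihood is
#' the plug-in sum over locations; referred to chi-squared with k degrees
#' of freedom.
#'
#' @param fit a \code{gwgpr_fit}.
#' @param null_fit optional explicit null fit (defaults to the one stored
#'   during fitting).
#' @param alpha significance level.
#' @return An \code{lr_test} record.
#' @export
gwgpr_simultaneous_test <- function(fit, null_fit = NULL, alpha = 0.05) {
  ll_null <- if (is.null(null_fit)) fit$loglik_null else null_fit$loglik
  D <- max(0, -2 * (ll_null - fit$loglik))
  k <- fit$k
  crit <- stats::qchisq(1 - alpha, df = k)
  structure(list(statistic = D, df = k, critical = crit,
                 p.value = stats::pchisq(D, df = k, lower.tail = FALSE),
                 reject = D > crit, alpha = alpha),
            class = "lr_test")
}

#' Per-location, per-parameter Wald tests for a GWGPR fit
#'
#' \code{Z_p(u_i, v_i) = beta_p(u_i, v_i) / se_p(u_i, v_i)}; a predictor is
#' significant at location i iff \code{|Z| > z(alpha/2)} (strict
#' inequality). Zero or non-finite standard errors are flagged
#' indeterminate.
#'
#' @param fit a \code{gwgpr_fit}.
#' @param alpha significance level.
#' @return Long-format data frame: \code{location}, \code{label},
#'   \code{parameter}, \code{estimate}, \code{se}, \code{z},
#'   \code{p.value}, \code{significant}, \code{indeterminate}.
#' @export
gwgpr_partial_tests <- function(fit, alpha = 0.05) {
  zcrit <- stats::qnorm(1 - alpha / 2)
  pn <- colnames(fit$beta)
  out <- do.call(rbind, lapply(seq_len(fit$n), function(i) {
    se <- fit$se[i, ]
    indet <- !is.finite(se) | se == 0
    z <- ifelse(indet, NA_real_, fit$beta[i, ] / se)
    data.frame(location = i, label = fit$location_labels[i],
               parameter = pn, estimate = unname(fit$beta[i, ]),
               se = unname(se), z = unname(z),
               p.value = unname(2 * stats::pnorm(-abs(z))),
               significant = unname(!indet & abs(z) > zcrit),
               indeterminate = unname(indet),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

significant_sets_from_partial <- function(partial, ds) {
  slopes <- partial[partial$parameter != "(Intercept)", ]
  lapply(seq_len(ds$n), function(i) {
    sub <- slopes[slopes$location == i & slopes$significant, "parameter"]
    sort(sub)
  })
}

#' Group locations by identical significant-variable sets
#'
#' Partitions the locations so that two locations share a group iff the
#' sets of predictors flagged significant by the partial tests are exactly
#' equal (the empty set is a valid key). Groups are ordered by descending
#' size.
#'
#' @param fit a \code{gwgpr_fit} with partial tests computed.
#' @return List of class \code{significance_groups}; each element has
#'   \code{variables}, \code{members} (labels), \code{indices}, \code{size}.
#' @export
significance_groups <- function(fit) {
  sets <- fit$significant_sets
  keys <- vapply(sets, function(s) paste(s, collapse = "+"), character(1))
  uk <- unique(keys)
  groups <- lapply(uk, function(kk) {
    idx <- which(keys == kk)
    list(variables = sets[[idx[1]]],
         members = fit$location_labels[idx],
         indices = idx, size = length(idx))
  })
  groups <- groups[order(vapply(groups, `[[`, integer(1), "size"),
                         decreasing = TRUE)]
  structure(groups, class = "significance_groups")
}

#' @export
print.significance_groups <- function(x, ...) {
  for (i in seq_along(x)) {
    g <- x[[i]]
    vars <- if (length(g$variables)) paste(g$variables, collapse = ", ") else "(none)"
    cat(sprintf("Group %d (%d location(s)) - significant: %s\n", i, g$size, vars))
    cat("  ", paste(g$members, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Akaike information criterion for fitted models
#'
#' \code{AIC = -2 lnL + 2 p} with p the number of estimated parameters:
#' k + 1 for Poisson regression, k + 2 for GPR (dispersion included), and
#' k + 2 for GWGPR (a recognised simplification: the effective number of
#' parameters of a locally weighted model is larger, but no hat-matrix
#' trace is defined for this likelihood). Smaller is better.
#'
#' @param fit a \code{poisson_fit}, \code{gpr_fit} or \code{gwgpr_fit}.
#' @return Scalar AIC.
#' @export
model_aic <- function(fit) UseMethod("model_aic")

#' @export
model_aic.poisson_fit <- function(fit) fit$aic

#' @export
model_aic.gpr_fit <- function(fit) fit$aic

#' @export
model_aic.gwgpr_fit <- function(fit) fit$aic

#' Export local GWGPR coefficients as a data frame
#'
#' @param fit a \code{gwgpr_fit}.
#' @return Data frame keyed by location label: coordinates are not stored
#'   in the fit, so columns are label, local coefficients, phi, fitted mean
#'   and convergence flag.
#' @export
gwgpr_coefficients <- function(fit) {
  stopifnot(inherits(fit, "gwgpr_fit"))
  data.frame(label = fit$location_labels, fit$beta, phi = fit$phi,
             fitted = fit$fitted, converged = fit$converged,
             check.names = FALSE, stringsAsFactors = FALSE)
}
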
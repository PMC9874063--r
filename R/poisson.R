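#' Poisson regression log-likelihood
#'
#' \code{sum_i [y_i eta_i - exp(eta_i) - log(y_i!)]} with
#' \code{eta = beta0 + X beta}. The factorial term uses \code{lgamma}.
#'
#' @param beta coefficient vector of length k + 1 (intercept first).
#' @param ds a \code{\link{spatial_count_dataset}}.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(beta, ds) {
  stopifnot(inherits(ds, "spatial_count_dataset"))
  if (length(beta) != ds$k + 1L)
    stop("poisson_loglik: beta must have length k + 1")
  eta <- drop(cbind(1, ds$X) %*% beta)
  if (any(eta > 700))
    stop("poisson_loglik: exp(eta) overflows; consider rescaling predictors")
  sum(ds$y * eta - exp(eta) - lgamma(ds$y + 1))
}

# Intercept-only Poisson log-likelihood (closed form: MLE of mean is ybar).
poisson_loglik_null <- function(y) {
  ybar <- mean(y)
  if (ybar <= 0) return(0)  # all-zero counts: supremum as beta0 -> -Inf
  sum(ifelse(y > 0, y * log(ybar), 0) - ybar - lgamma(y + 1))
}

#' Fit a global Poisson regression by Newton-Raphson
#'
#' Maximum likelihood with a log link. Iterates
#' \code{beta <- beta - H^-1 g} from a least-squares start on
#' \code{log(y + 1)}, with step-halving whenever a full Newton step would
#' decrease the log-likelihood or leave the finite domain. Standard errors
#' come from the inverse observed information.
#'
#' @param ds a \code{\link{spatial_count_dataset}}.
#' @param tol convergence tolerance on the infinity norm of the parameter
#'   change (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100). If reached, the
#'   fit is returned with \code{converged = FALSE} and a warning.
#' @return Object of class \code{poisson_fit}: \code{coefficients},
#'   \code{se}, \code{loglik}, \code{loglik_null}, \code{deviance}
#'   (\code{-2 (lnL_null - lnL)}), \code{aic} (\code{-2 lnL + 2 (k+1)}),
#'   \code{fitted}, \code{linear_predictors}, \code{n_iter},
#'   \code{converged}, \code{n}, \code{k}.
#' @examples
#' ds <- spatial_count_dataset(rpois(30, 3), cbind(x = rnorm(30)),
#'                             cbind(runif(30), runif(30)))
#' fit <- fit_poisson(ds)
#' coef(fit)
#' @export
fit_poisson <- function(ds, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(ds, "spatial_count_dataset"))
  y <- ds$y
  A <- cbind("(Intercept)" = 1, ds$X)
  p <- ncol(A)

  beta <- stats::lm.fit(A, log(y + 1))$coefficients
  beta[!is.finite(beta)] <- 0
  ll <- tryCatch(poisson_loglik(beta, ds), error = function(e) -Inf)
  n_iter <- 0L
  converged <- FALSE
  for (m in seq_len(max_iter)) {
    n_iter <- m
    eta <- drop(A %*% beta)
    mu <- exp(eta)
    g <- crossprod(A, y - mu)
    info <- crossprod(A, A * mu)  # negative Hessian
    step <- tryCatch(solve(info, g), error = function(e)
      stop(sprintf("fit_poisson: singular Hessian at iteration %d (reciprocal condition %.3e); check for collinear or unscaled predictors",
                   m, rcond(info)), call. = FALSE))
    # step-halving safeguard: pure Newton can overshoot on the log scale
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- tryCatch(poisson_loglik(cand, ds), error = function(e) NaN)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 2^-30)
        stop("fit_poisson: step-halving exhausted; log-likelihood cannot be increased", call. = FALSE)
    }
    delta <- max(abs(lam * step))
    beta <- cand
    ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("fit_poisson: not converged after %d iterations", max_iter))

  eta <- drop(A %*% beta)
  mu <- exp(eta)
  info <- crossprod(A, A * mu)
  se <- sqrt(diag(solve(info)))
  names(se) <- colnames(A)
  ll_null <- poisson_loglik_null(y)
  D <- -2 * (ll_null - ll)
  structure(list(coefficients = stats::setNames(drop(beta), colnames(A)),
                 se = se, loglik = ll, loglik_null = ll_null,
                 deviance = max(0, D), aic = -2 * ll + 2 * p,
                 fitted = mu, linear_predictors = eta,
                 n_iter = n_iter, converged = converged,
                 n = ds$n, k = ds$k, predictor_names = ds$predictor_names),
            class = "poisson_fit")
}

#' @export
coef.poisson_fit <- function(object, ...) object$coefficients

#' @export
logLik.poisson_fit <- function(object, ...) {
  structure(object$loglik, df = object$k + 1L, class = "logLik")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("Global Poisson regression (Newton-Raphson MLE)\n")
  wt <- wald_tests(x)
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               `z value` = wt$z, `Pr(>|z|)` = wt$p.value)
  stats::printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("Deviance (vs intercept-only): %.4f   logLik: %.4f   AIC: %.4f\n",
              x$deviance, x$loglik, x$aic))
  if (!x$converged) cat("WARNING: Newton-Raphson did not converge\n")
  invisible(x)
}

#' Simultaneous (likelihood-ratio) test of all slopes
#'
#' Compares the fitted model with the intercept-only model:
#' \code{D = -2 (lnL_null - lnL)} referred to chi-squared with k degrees of
#' freedom. H0 (all slopes zero) is rejected when D strictly exceeds the
#' critical value.
#'
#' @param fit a \code{poisson_fit} (or any object with \code{loglik},
#'   \code{loglik_null}, \code{k}).
#' @param alpha significance level.
#' @return List of class \code{lr_test}: \code{statistic}, \code{df},
#'   \code{critical}, \code{p.value}, \code{reject}.
#' @export
deviance_test <- function(fit, alpha = 0.05) {
  D <- -2 * (fit$loglik_null - fit$loglik)
  D <- max(0, D)
  k <- fit$k
  crit <- stats::qchisq(1 - alpha, df = k)
  structure(list(statistic = D, df = k, critical = crit,
                 p.value = stats::pchisq(D, df = k, lower.tail = FALSE),
                 reject = D > crit, alpha = alpha),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: D = %.4f on %d df (critical %.3f, p = %.4g) -> %s\n",
              x$statistic, x$df, x$critical, x$p.value,
              if (x$reject) "reject H0: at least one slope is non-zero"
              else "fail to reject H0"))
  invisible(x)
}

#' Per-parameter Wald tests
#'
#' \code{Z_p = beta_p / se_p}; a parameter is significant at level alpha
#' iff \code{|Z| > z(alpha/2)} (strict inequality, so |Z| exactly at the
#' critical value is not significant). Zero standard errors are flagged
#' indeterminate rather than producing infinite Z.
#'
#' @param fit a \code{poisson_fit} or \code{gpr_fit}.
#' @param alpha significance level.
#' @return Data frame: \code{parameter}, \code{estimate}, \code{se},
#'   \code{z}, \code{p.value}, \code{significant}, \code{indeterminate}.
#' @export
wald_tests <- function(fit, alpha = 0.05) {
  est <- fit$coefficients
  se <- fit$se
  zcrit <- stats::qnorm(1 - alpha / 2)
  indet <- !is.finite(se) | se == 0
  z <- ifelse(indet, NA_real_, est / se)
  data.frame(parameter = names(est), estimate = unname(est), se = unname(se),
             z = unname(z),
             p.value = unname(2 * stats::pnorm(-abs(z))),
             significant = unname(!indet & abs(z) > zcrit),
             indeterminate = unname(indet),
             stringsAsFactors = FALSE)
}
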
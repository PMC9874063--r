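#' Generalized Poisson log-probability mass
#'
#' Log density of the generalized Poisson distribution with mean mu and
#' dispersion phi:
#' \deqn{\log f(y) = y \log\frac{\mu}{1+\phi\mu} + (y-1)\log(1+\phi y)
#'   - \log y! - \frac{\mu(1+\phi y)}{1+\phi\mu}.}
#' \code{phi = 0} recovers the Poisson log-pmf; \code{phi > 0} gives
#' overdispersion with variance \code{mu (1 + phi mu)^2}, \code{phi < 0}
#' underdispersion on the truncated support where \code{1 + phi y > 0}.
#'
#' @param y non-negative integer count(s).
#' @param mu mean(s), strictly positive.
#' @param phi dispersion scalar; must satisfy \code{1 + phi mu > 0} and
#'   \code{1 + phi y > 0}.
#' @return Log-probability, vectorised over \code{y} and \code{mu}.
#' @examples
#' gp_logpmf(2, 1, 0)          # Poisson reduction: -1 - log(2)
#' gp_logpmf(0, 2, 0.5)        # -mu (1)/(1 + phi mu) = -1
#' @export
gp_logpmf <- function(y, mu, phi) {
  if (any(mu <= 0)) stop("gp_logpmf: mu must be strictly positive")
  if (any(1 + phi * mu <= 0))
    stop("gp_logpmf: support constraint 1 + phi*mu > 0 violated")
  if (any(1 + phi * y <= 0))
    stop("gp_logpmf: support constraint 1 + phi*y > 0 violated")
  y * log(mu / (1 + phi * mu)) + (y - 1) * log1p(phi * y) -
    lgamma(y + 1) - mu * (1 + phi * y) / (1 + phi * mu)
}

# ---- internal generalized Poisson likelihood machinery -------------------
# All fitting (global GPR and local GWGPR) goes through gpr_engine(), a
# weighted maximum-likelihood driver: Newton-Raphson for beta at fixed phi
# (with step-halving), alternated with a dispersion update (moments or
# Newton), to joint convergence in the infinity norm.

# per-observation derivative of the GP loglik wrt eta (mu = exp(eta))
gp_score_eta <- function(y, mu, phi) {
  y / (1 + phi * mu) - mu * (1 + phi * y) / (1 + phi * mu)^2
}

# per-observation second derivative wrt eta
gp_hess_eta <- function(y, mu, phi) {
  -(y * phi * mu / (1 + phi * mu)^2 +
      (1 + phi * y) * mu * (1 - phi * mu) / (1 + phi * mu)^3)
}

# derivatives of the GP loglik wrt phi at fixed beta
gp_score_phi <- function(y, mu, phi, w) {
  sum(w * (-y * mu / (1 + phi * mu) + y * (y - 1) / (1 + phi * y) -
             mu * (y - mu) / (1 + phi * mu)^2))
}

gp_hess_phi <- function(y, mu, phi, w) {
  sum(w * (y * mu^2 / (1 + phi * mu)^2 - y^2 * (y - 1) / (1 + phi * y)^2 +
             2 * mu^2 * (y - mu) / (1 + phi * mu)^3))
}

# smallest admissible phi for given counts and means, plus safety margin
phi_lower_bound <- function(y, mu) {
  -1 / max(max(y), max(mu))
}

# Weighted GP log-likelihood, -Inf outside the admissible region.
# Fitted means are capped at 50 x (1 + the largest positively weighted
# count): for phi > 0 the per-observation GP terms flatten as mu grows (a
# zero count costs only -1/phi, a positive count approaches
# y log(1/phi) - (1 + phi y)/phi), so the likelihood has near-plateau
# directions along which beta can run away, and the alternating beta/phi
# scheme can drift onto a degenerate mode with enormous means and phi
# pinned near zero - especially in small kernel windows mixing very small
# and very large counts. No admissible mean for count data exceeds the
# observed counts by orders of magnitude, so the cap removes those modes
# without constraining a realistic fit.
gp_wloglik <- function(y, A, beta, phi, w) {
  idx <- w > 0
  eta <- drop(A[idx, , drop = FALSE] %*% beta)
  if (any(eta > log(50 * (max(y[idx]) + 1)))) return(-Inf)
  mu <- exp(eta)
  if (any(1 + phi * mu <= 0) || any(1 + phi * y[idx] <= 0)) return(-Inf)
  sum(w[idx] * gp_logpmf(y[idx], mu, phi))
}

# Newton-Raphson for beta at fixed phi, weighted; step-halving + ridge retry
gpr_newton_beta <- function(y, A, w, beta, phi, tol, max_iter) {
  ll <- gp_wloglik(y, A, beta, phi, w)
  if (!is.finite(ll)) stop("gpr_newton_beta: infeasible starting value")
  iters <- 0L
  for (m in seq_len(max_iter)) {
    iters <- m
    mu <- exp(drop(A %*% beta))
    s <- gp_score_eta(y, mu, phi)
    h <- gp_hess_eta(y, mu, phi)
    g <- crossprod(A, w * s)
    H <- crossprod(A, A * (w * h))
    step <- tryCatch(solve(-H, g), error = function(e) NULL)
    if (is.null(step)) {  # ridge jitter then retry once
      Hr <- H - diag(1e-8, ncol(A))
      step <- tryCatch(solve(-Hr, g), error = function(e)
        stop("gpr_newton_beta: singular Hessian even after ridge jitter", call. = FALSE))
    }
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- gp_wloglik(y, A, cand, phi, w)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 2^-30) { cand <- beta; ll_new <- ll; break }
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    ll <- ll_new
    if (delta < tol) break
  }
  list(beta = beta, loglik = ll, n_iter = iters)
}

# Moments update for phi: solve the Pearson condition
#   sum w (y - mu)^2 / [mu (1 + phi mu)^2] = sum(w) - p
# by safeguarded Newton (the left side is strictly decreasing in phi).
gpr_phi_moments <- function(y, mu, w, phi, p, lower, tol = 1e-10, max_iter = 100L) {
  target <- sum(w) - p
  if (target <= 0) return(NULL)  # too little effective data; caller falls back
  Q <- function(ph) sum(w * (y - mu)^2 / (mu * (1 + ph * mu)^2))
  Qp <- function(ph) -2 * sum(w * (y - mu)^2 / (1 + ph * mu)^3)
  for (m in seq_len(max_iter)) {
    q <- Q(phi)
    step <- -(q - target) / Qp(phi)
    phi_new <- phi + step
    if (phi_new <= lower) phi_new <- (phi + lower) / 2
    if (abs(phi_new - phi) < tol) return(phi_new)
    phi <- phi_new
  }
  phi
}

# Newton ascent in phi on the weighted log-likelihood at fixed beta
gpr_phi_newton <- function(y, mu, w, phi, lower, upper_guard = 1e6,
                           tol = 1e-10, max_iter = 100L) {
  ll_at <- function(ph) {
    if (ph <= lower || any(1 + ph * y[w > 0] <= 0)) return(-Inf)
    sum(w * gp_logpmf(y, mu, ph))
  }
  ll <- ll_at(phi)
  for (m in seq_len(max_iter)) {
    g <- gp_score_phi(y, mu, phi, w)
    h <- gp_hess_phi(y, mu, phi, w)
    step <- if (is.finite(h) && h < 0) -g / h else sign(g) * 0.1
    lam <- 1
    repeat {
      cand <- phi + lam * step
      ll_new <- ll_at(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 2^-30) { cand <- phi; ll_new <- ll; break }
    }
    moved <- abs(cand - phi)
    phi <- cand; ll <- ll_new
    if (moved < tol) break
  }
  phi
}

# Weighted generalized Poisson ML driver. A includes the intercept column.
gpr_engine <- function(y, A, w = rep(1, length(y)),
                       phi_mode = c("moments", "newton"),
                       beta_init = NULL, phi_init = 0,
                       est_phi = TRUE, tol = 1e-8, max_iter = 100L) {
  phi_mode <- match.arg(phi_mode)
  keep <- w > 0
  if (!all(keep)) { y <- y[keep]; A <- A[keep, , drop = FALSE]; w <- w[keep] }
  p <- ncol(A)
  if (is.null(beta_init)) {
    beta_init <- stats::lm.fit(A * sqrt(w), sqrt(w) * log(y + 1))$coefficients
    beta_init[!is.finite(beta_init)] <- 0
  }
  beta <- beta_init
  phi <- phi_init
  converged <- FALSE
  n_iter <- 0L
  clamped <- FALSE
  for (outer in seq_len(max_iter)) {
    n_iter <- outer
    nb <- gpr_newton_beta(y, A, w, beta, phi, tol, max_iter)
    beta_new <- nb$beta
    mu <- exp(drop(A %*% beta_new))
    phi_new <- phi
    if (est_phi) {
      lower <- phi_lower_bound(y[w > 0], mu[w > 0]) + 1e-6
      phi_new <- if (phi_mode == "moments")
        gpr_phi_moments(y, mu, w, phi, p, lower) else NULL
      if (is.null(phi_new))  # moments target infeasible -> likelihood route
        phi_new <- gpr_phi_newton(y, mu, w, phi, lower)
      if (phi_new <= lower) { phi_new <- lower; clamped <- TRUE }
    }
    delta <- max(abs(beta_new - beta), abs(phi_new - phi))
    beta <- beta_new
    phi <- phi_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (clamped)
    warning("gpr_engine: dispersion clamped at the lower support bound")
  mu <- exp(drop(A %*% beta))
  ll <- gp_wloglik(y, A, beta, phi, w)
  # observed information for beta at the optimum
  H <- crossprod(A, A * (w * gp_hess_eta(y, mu, phi)))
  cov_beta <- tryCatch(solve(-H), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(0, diag(cov_beta)))
  # se(phi): numerical second derivative of the profile log-likelihood
  se_phi <- NA_real_
  if (est_phi) {
    hstep <- max(1e-5, abs(phi) * 1e-3)
    prof <- function(ph) {
      nb <- tryCatch(gpr_newton_beta(y, A, w, beta, ph, tol, max_iter),
                     error = function(e) NULL)
      if (is.null(nb)) return(NA_real_) else nb$loglik
    }
    l0 <- ll
    lp <- prof(phi + hstep); lm_ <- prof(phi - hstep)
    if (is.finite(lp) && is.finite(lm_)) {
      d2 <- (lp - 2 * l0 + lm_) / hstep^2
      if (is.finite(d2) && d2 < 0) se_phi <- sqrt(-1 / d2)
    }
  }
  list(beta = beta, phi = phi, se = se, se_phi = se_phi, cov_beta = cov_beta,
       loglik = ll, mu = mu, n_iter = n_iter, converged = converged)
}

#' Fit a global generalized Poisson regression
#'
#' Maximum likelihood for the generalized Poisson model
#' \code{mu = exp(X' beta)} with dispersion \code{phi}. The mean
#' coefficients are updated by Newton-Raphson (with step-halving) at the
#' current \code{phi}; \code{phi} is then updated either by the
#' method-of-moments iteration that equates the Pearson chi-squared
#' statistic \code{sum (y - mu)^2 / [mu (1 + phi mu)^2]} with its degrees of
#' freedom \code{n - (k + 1)} (the default), or by Newton ascent on the
#' profile log-likelihood (\code{phi_mode = "newton"}). The two updates
#' alternate until the joint parameter change falls below \code{tol}.
#'
#' Initialisation: \code{beta} from the global Poisson fit, \code{phi = 0}.
#' \code{phi} is clamped just above its support bound
#' \code{-1 / max(max(y), max(mu))} if an update would leave the domain.
#'
#' @param ds a \code{\link{spatial_count_dataset}}.
#' @param phi_mode \code{"moments"} (default) or \code{"newton"}.
#' @param tol joint convergence tolerance (infinity norm), default 1e-8.
#' @param max_iter maximum outer iterations.
#' @return Object of class \code{gpr_fit}: \code{coefficients}, \code{phi},
#'   \code{se}, \code{se_phi}, \code{loglik}, \code{loglik_null}
#'   (intercept-only GPR on the same data), \code{deviance}, \code{aic}
#'   (\code{-2 lnL + 2 (k + 2)}: intercept, k slopes, phi), \code{fitted},
#'   \code{pearson_ratio}, \code{n_iter}, \code{converged}.
#' @export
fit_gpr <- function(ds, phi_mode = c("moments", "newton"),
                    tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(ds, "spatial_count_dataset"))
  phi_mode <- match.arg(phi_mode)
  y <- ds$y
  A <- cbind("(Intercept)" = 1, ds$X)
  pois <- fit_poisson(ds, tol = tol, max_iter = max_iter)
  eng <- gpr_engine(y, A, phi_mode = phi_mode,
                    beta_init = pois$coefficients, phi_init = 0,
                    tol = tol, max_iter = max_iter)
  if (!eng$converged)
    warning(sprintf("fit_gpr: not converged after %d outer iterations", max_iter))
  # intercept-only log-likelihood at the full model's dispersion estimate:
  # holding phi fixed keeps the models nested (deviance >= 0) and gives the
  # profile likelihood-ratio statistic its chi-squared null distribution,
  # which a separately moment-estimated null phi would not
  null_eng <- gpr_engine(y, matrix(1, ds$n, 1), phi_mode = phi_mode,
                         beta_init = log(max(mean(y), 1e-8)),
                         phi_init = eng$phi, est_phi = FALSE,
                         tol = tol, max_iter = max_iter)
  pearson <- sum((y - eng$mu)^2 / (eng$mu * (1 + eng$phi * eng$mu)^2))
  structure(list(coefficients = stats::setNames(eng$beta, colnames(A)),
                 phi = eng$phi,
                 se = stats::setNames(eng$se, colnames(A)),
                 se_phi = eng$se_phi,
                 loglik = eng$loglik, loglik_null = null_eng$loglik,
                 deviance = max(0, -2 * (null_eng$loglik - eng$loglik)),
                 aic = -2 * eng$loglik + 2 * (ds$k + 2L),
                 fitted = eng$mu,
                 pearson = pearson,
                 pearson_ratio = pearson / (ds$n - ds$k - 1L),
                 phi_mode = phi_mode,
                 n_iter = eng$n_iter, converged = eng$converged,
                 n = ds$n, k = ds$k, predictor_names = ds$predictor_names),
            class = "gpr_fit")
}

#' @export
coef.gpr_fit <- function(object, ...) object$coefficients

#' @export
logLik.gpr_fit <- function(object, ...) {
  structure(object$loglik, df = object$k + 2L, class = "logLik")
}

#' @export
print.gpr_fit <- function(x, ...) {
  cat(sprintf("Generalized Poisson regression (phi by %s)\n", x$phi_mode))
  wt <- gpr_wald(x)
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               `z value` = wt$z, `Pr(>|z|)` = wt$p.value)
  stats::printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("phi: %.5f (se %.5f)   Pearson/df: %.4f\n",
              x$phi, x$se_phi, x$pearson_ratio))
  cat(sprintf("Deviance (vs intercept-only GPR): %.4f   logLik: %.4f   AIC: %.4f\n",
              x$deviance, x$loglik, x$aic))
  if (!x$converged) cat("WARNING: estimation did not converge\n")
  invisible(x)
}

#' Maximum likelihood ratio test for a GPR fit
#'
#' \code{D = -2 (lnL_null - lnL_full)} against the intercept-only (+phi)
#' model, referred to chi-squared with k degrees of freedom.
#'
#' @param fit a \code{gpr_fit}.
#' @param null_fit optional explicit intercept-only fit; by default the
#'   null log-likelihood stored in \code{fit} is used.
#' @param alpha significance level.
#' @return An \code{lr_test} record as for \code{\link{deviance_test}}.
#' @export
gpr_mlrt <- function(fit, null_fit = NULL, alpha = 0.05) {
  ll_null <- if (is.null(null_fit)) fit$loglik_null else null_fit$loglik
  D <- -2 * (ll_null - fit$loglik)
  if (D < -1e-6)
    stop("gpr_mlrt: full-model log-likelihood below the null model's; optimization failure")
  D <- max(0, D)
  k <- fit$k
  crit <- stats::qchisq(1 - alpha, df = k)
  structure(list(statistic = D, df = k, critical = crit,
                 p.value = stats::pchisq(D, df = k, lower.tail = FALSE),
                 reject = D > crit, alpha = alpha),
            class = "lr_test")
}

#' Wald tests for GPR coefficients
#'
#' \code{W_p = beta_p / se_p}, significant at level alpha iff
#' \code{|W| > z(alpha/2)} (strict).
#'
#' @param fit a \code{gpr_fit}.
#' @param alpha significance level.
#' @return Data frame as in \code{\link{wald_tests}}.
#' @export
gpr_wald <- function(fit, alpha = 0.05) wald_tests(fit, alpha = alpha)
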
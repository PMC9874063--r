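#' Variance inflation factors
#'
#' For every predictor j, regresses column j on all remaining predictors
#' (with intercept) by least squares and reports
#' \code{VIF_j = 1 / (1 - R2_j)}. Values above the threshold (default 10)
#' flag multicollinearity; exact collinearity is reported as an infinite VIF
#' rather than an error.
#'
#' @param X numeric predictor matrix, n rows, k >= 2 columns.
#' @param threshold flag level for the multicollinearity warning column.
#' @return A data frame of class \code{vif_report} with columns
#'   \code{predictor}, \code{r_squared}, \code{vif}, \code{flagged}.
#' @export
vif <- function(X, threshold = 10) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (k < 2L) stop("vif: need at least two predictors")
  if (n <= k) stop("vif: need n > k observations")
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  r2 <- numeric(k)
  for (j in seq_len(k)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    sst <- sum((X[, j] - mean(X[, j]))^2)
    r2[j] <- if (sst <= 0) 1 else max(0, 1 - sum(res^2) / sst)
  }
  tol <- 1e-12
  v <- ifelse(r2 >= 1 - tol, Inf, 1 / (1 - r2))
  out <- data.frame(predictor = nm, r_squared = r2, vif = v,
                    flagged = v > threshold, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("vif_report", "data.frame")
  out
}

# Asymptotic upper tail of the Kolmogorov distribution:
# P(sqrt(n) D > t) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 t^2)
kolmogorov_pvalue <- function(t) {
  if (t <= 0) return(1)
  j <- seq_len(101)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  min(1, max(0, p))
}

#' Kolmogorov-Smirnov goodness of fit to the Poisson distribution
#'
#' Tests whether counts are compatible with a Poisson distribution whose
#' mean is estimated by the sample mean. The statistic is the standard
#' two-sided D over the sorted sample,
#' \code{D = max_i max(i/N - F(y_(i)), F(y_(i)) - (i-1)/N)} with F the
#' Poisson CDF. The p-value uses the asymptotic Kolmogorov distribution.
#' With discrete data the lower envelope term \code{F(y) - (i-1)/N} absorbs
#' the CDF jump at tied values, so D is inflated by roughly the largest pmf
#' mass and the test over-rejects for heavily tied samples; the statistic
#' is reported as defined rather than corrected, and should be read as a
#' screening device.
#'
#' @param y counts, length >= 5.
#' @param alpha significance level for the decision.
#' @return List of class \code{ks_poisson} with \code{statistic} (D in
#'   [0,1]), \code{mean}, \code{p.value}, \code{alpha}, \code{reject}.
#' @export
ks_poisson <- function(y, alpha = 0.05) {
  if (length(y) < 5L) stop("ks_poisson: need at least 5 observations")
  n <- length(y)
  lambda <- mean(y)
  if (lambda <= 0) {
    warning("ks_poisson: all counts are zero; Poisson mean floored at a machine-safe positive value")
    lambda <- .Machine$double.xmin^0.25
  }
  ys <- sort(y)
  Fv <- stats::ppois(ys, lambda)
  i <- seq_len(n)
  D <- max(pmax(i / n - Fv, Fv - (i - 1) / n))
  p <- kolmogorov_pvalue(sqrt(n) * D)
  structure(list(statistic = D, mean = lambda, p.value = p, alpha = alpha,
                 reject = p <= alpha, n = n),
            class = "ks_poisson")
}

#' @export
print.ks_poisson <- function(x, ...) {
  cat(sprintf("Kolmogorov-Smirnov test vs Poisson(mean = %.4f): D = %.4f, p = %.4g -> %s at alpha = %g\n",
              x$mean, x$statistic, x$p.value,
              if (x$reject) "reject Poisson" else "fail to reject Poisson", x$alpha))
  invisible(x)
}

#' Breusch-Pagan test for spatial heterogeneity
#'
#' Score test for non-constant residual variance, used here as evidence of
#' spatial heterogeneity justifying a locally weighted model. With residuals
#' e from a global fit, \code{sigma2 = mean(e^2)},
#' \code{f_i = e_i^2 / sigma2 - 1}, and Z the n x (k+1) matrix of an
#' intercept column plus column-standardised predictors, the statistic is
#' \code{BP = 0.5 * t(f) Z (Z'Z)^-1 Z' f}, referred to a chi-squared
#' distribution with k degrees of freedom.
#'
#' The centred form of f is used (rather than e^2/sigma2 alone) so that the
#' chi-squared reference distribution is valid.
#'
#' @param e residuals, typically raw residuals y - mu from a Poisson fit.
#' @param Zraw n x k predictor matrix on its raw scale (no intercept);
#'   columns are standardised internally.
#' @param alpha significance level.
#' @return List of class \code{bp_test} with \code{statistic}, \code{df},
#'   \code{p.value}, \code{critical}, \code{reject}, \code{sigma2}, \code{f}.
#' @export
breusch_pagan <- function(e, Zraw, alpha = 0.05) {
  Zraw <- as.matrix(Zraw)
  n <- length(e); k <- ncol(Zraw)
  if (nrow(Zraw) != n) stop("breusch_pagan: residuals and predictors must have equal length")
  if (n <= k + 1L) stop("breusch_pagan: need n > k + 1")
  sds <- apply(Zraw, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("breusch_pagan: constant predictor column(s): %s",
                 paste(which(sds == 0), collapse = ", ")))
  Z <- cbind(1, scale(Zraw))
  ZtZ <- crossprod(Z)
  qrz <- qr(ZtZ)
  if (qrz$rank < ncol(Z)) {
    cc <- qrz$pivot[seq(qrz$rank + 1L, ncol(Z))] - 1L
    stop(sprintf("breusch_pagan: Z'Z is singular; collinear predictor column(s): %s",
                 paste(cc, collapse = ", ")))
  }
  sigma2 <- mean(e^2)
  f <- e^2 / sigma2 - 1
  Ztf <- crossprod(Z, f)
  bp <- 0.5 * drop(crossprod(Ztf, solve(ZtZ, Ztf)))
  crit <- stats::qchisq(1 - alpha, df = k)
  structure(list(statistic = bp, df = k,
                 p.value = stats::pchisq(bp, df = k, lower.tail = FALSE),
                 critical = crit, reject = bp > crit, alpha = alpha,
                 sigma2 = sigma2, f = f),
            class = "bp_test")
}

#' @export
print.bp_test <- function(x, ...) {
  cat(sprintf("Breusch-Pagan test: BP = %.4f on %d df, p = %.4g (critical %.3f) -> %s\n",
              x$statistic, x$df, x$p.value, x$critical,
              if (x$reject) "variance differs between locations"
              else "no evidence of spatial heterogeneity"))
  invisible(x)
}

#' Dispersion classification for a Poisson fit
#'
#' Divides the deviance or Pearson chi-squared statistic by the residual
#' degrees of freedom. A ratio above 1 indicates overdispersion, below 1
#' underdispersion; a ratio within 1e-9 of 1 is classified equidispersed.
#'
#' @param observed observed counts.
#' @param fitted fitted means, strictly positive.
#' @param n_params number of estimated mean parameters (k + 1 with an
#'   intercept).
#' @param mode \code{"deviance"} (2 sum[y log(y/mu) - (y - mu)], with
#'   0 log 0 := 0) or \code{"pearson"} (sum (y - mu)^2 / mu).
#' @return List of class \code{dispersion_result} with \code{statistic},
#'   \code{df}, \code{ratio}, \code{classification}.
#' @export
dispersion_statistic <- function(observed, fitted, n_params,
                                 mode = c("deviance", "pearson")) {
  mode <- match.arg(mode)
  y <- as.numeric(observed); mu <- as.numeric(fitted)
  if (any(mu <= 0)) stop("dispersion_statistic: fitted means must be strictly positive")
  df <- length(y) - n_params
  if (df <= 0) stop("dispersion_statistic: residual degrees of freedom must be positive")
  stat <- if (mode == "deviance") {
    term <- ifelse(y > 0, y * log(y / mu), 0)
    2 * sum(term - (y - mu))
  } else {
    sum((y - mu)^2 / mu)
  }
  classify_dispersion(stat, df, mode)
}

classify_dispersion <- function(stat, df, mode) {
  ratio <- stat / df
  cls <- if (abs(ratio - 1) <= 1e-9) "equidispersed"
         else if (ratio > 1) "overdispersed" else "underdispersed"
  structure(list(statistic = stat, df = df, ratio = ratio,
                 classification = cls, mode = mode),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Dispersion (%s): statistic %.4f / df %d = %.4f -> %s\n",
              x$mode, x$statistic, x$df, x$ratio, x$classification))
  invisible(x)
}

#' Pre-fit and post-fit diagnostics for a spatial count dataset
#'
#' Runs, in order: VIF multicollinearity screening, the Kolmogorov-Smirnov
#' Poisson goodness-of-fit test, a global Poisson fit, the dispersion ratio
#' of that fit, and the Breusch-Pagan spatial-heterogeneity test on its
#' residuals.
#'
#' By default Pearson residuals \code{(y - mu) / sqrt(mu)} are fed to the
#' BP test: under a correctly specified Poisson model the raw residual
#' \code{y - mu} has variance \code{mu_i}, which varies with the predictors
#' by construction, so BP on raw residuals flags mean structure as
#' heterogeneity even when none exists. Standardising restores the constant
#' null variance the chi-squared reference assumes.
#' \code{residual_type = "raw"} is available for comparison.
#'
#' @param ds a \code{\link{spatial_count_dataset}}.
#' @param alpha significance level used throughout.
#' @param vif_threshold VIF flag level.
#' @param residual_type residuals for the BP test: \code{"pearson"}
#'   (default) or \code{"raw"}.
#' @return List of class \code{diagnostics_report} with elements \code{vif},
#'   \code{ks}, \code{dispersion}, \code{bp}, \code{poisson_fit}.
#' @export
diagnose <- function(ds, alpha = 0.05, vif_threshold = 10,
                     residual_type = c("pearson", "raw")) {
  stopifnot(inherits(ds, "spatial_count_dataset"))
  residual_type <- match.arg(residual_type)
  v <- if (ds$k >= 2) vif(ds$X, threshold = vif_threshold) else NULL
  ks <- ks_poisson(ds$y, alpha = alpha)
  pf <- fit_poisson(ds)
  disp <- dispersion_statistic(ds$y, pf$fitted, n_params = ds$k + 1L,
                               mode = "deviance")
  e <- ds$y - pf$fitted
  if (residual_type == "pearson") e <- e / sqrt(pf$fitted)
  bp <- breusch_pagan(e, ds$X, alpha = alpha)
  structure(list(vif = v, ks = ks, dispersion = disp, bp = bp,
                 poisson_fit = pf, alpha = alpha),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("== Diagnostics ==\n")
  if (!is.null(x$vif)) {
    cat("VIF (threshold", attr(x$vif, "threshold"), "):\n")
    print.data.frame(x$vif, row.names = FALSE, digits = 4)
  }
  print(x$ks)
  print(x$dispersion)
  print(x$bp)
  if (!x$bp$reject)
    cat("Note: BP test does not reject homogeneity; spatial modelling not indicated.\n")
  invisible(x)
}
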
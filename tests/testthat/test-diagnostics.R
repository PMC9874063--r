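test_that("VIF is 1 for orthogonal predictors and infinite under exact collinearity", {
  X <- cbind(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1))  # mean-centred, orthogonal
  # need n > k: 4 > 2 ok
  v <- vif(X)
  expect_equal(v$vif, c(1, 1))
  expect_false(any(v$flagged))

  x1 <- rnorm(20)
  v2 <- vif(cbind(x1 = x1, x2 = 2 * x1))
  expect_true(all(is.infinite(v2$vif)))
  expect_true(all(v2$flagged))
})

test_that("VIF matches the auxiliary least-squares oracle and is permutation-stable", {
  set.seed(11)
  n <- 50
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  X[, 3] <- X[, 3] + 0.6 * X[, 1]
  v <- vif(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(v$vif[j], 1 / (1 - r2), tolerance = 1e-10)
  }
  perm <- c(3, 1, 2)
  vp <- vif(X[, perm])
  expect_equal(vp$vif, v$vif[perm], tolerance = 1e-12)
})

test_that("KS statistic agrees with the generic envelope oracle on Poisson draws", {
  set.seed(7)
  y <- rpois(500, 5)
  res <- ks_poisson(y)
  # independent oracle: classical one-sample KS machinery with the Poisson
  # CDF at the estimated mean, on the same draws
  or <- suppressWarnings(stats::ks.test(y, "ppois", mean(y)))
  expect_equal(res$statistic, unname(or$statistic), tolerance = 1e-12)
  expect_true(res$statistic >= 0 && res$statistic <= 1)
})

test_that("KS on a constant sample reproduces the hand-computed envelope", {
  res <- ks_poisson(rep(3, 50))
  FA <- ppois(3, 3)
  expect_equal(res$statistic, max(1 - FA, FA), tolerance = 1e-12)
  expect_true(res$reject)
})

test_that("KS statistic is bounded in [0, 1] across random count samples", {
  set.seed(5)
  for (rep in 1:10) {
    y <- rpois(sample(5:60, 1), runif(1, 0.5, 20))
    res <- ks_poisson(y)
    expect_gte(res$statistic, 0)
    expect_lte(res$statistic, 1)
  }
})

test_that("all-zero counts are handled with a floored mean and a warning", {
  expect_warning(res <- ks_poisson(rep(0L, 10)), "zero")
  expect_true(is.finite(res$statistic))
})

test_that("Breusch-Pagan vanishes for equal-magnitude residuals and matches the quadratic-form oracle", {
  Z <- cbind(x1 = rnorm(12), x2 = rnorm(12))
  e <- rep(c(2, -2), 6)
  res <- breusch_pagan(e, Z)
  expect_equal(res$statistic, 0, tolerance = 1e-20)
  expect_false(res$reject)

  set.seed(21)
  n <- 100
  Zr <- cbind(a = rnorm(n), b = runif(n))
  e <- rnorm(n, sd = exp(0.5 * Zr[, 1]))  # heteroskedastic
  res <- breusch_pagan(e, Zr)
  # direct matrix-arithmetic oracle
  Zs <- cbind(1, scale(Zr))
  f <- e^2 / mean(e^2) - 1
  bp_direct <- 0.5 * drop(t(f) %*% Zs %*% solve(t(Zs) %*% Zs) %*% t(Zs) %*% f)
  expect_equal(res$statistic, bp_direct, tolerance = 1e-10)
  expect_equal(res$df, 2L)
})

test_that("Breusch-Pagan is invariant to shifting a raw predictor column", {
  set.seed(22)
  n <- 60
  Zr <- cbind(a = rnorm(n), b = rnorm(n))
  e <- rnorm(n, sd = 1 + abs(Zr[, 1]))
  b1 <- breusch_pagan(e, Zr)$statistic
  Zr2 <- Zr; Zr2[, 2] <- Zr2[, 2] + 100
  b2 <- breusch_pagan(e, Zr2)$statistic
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("BP decision logic matches the published chi-squared comparison", {
  # a statistic of 17.802 on 5 df exceeds the 11.07 critical value
  expect_true(17.802 > qchisq(0.95, 5))
  expect_lt(pchisq(17.802, 5, lower.tail = FALSE), 0.05)
})

test_that("dispersion ratio classifies over/under/equidispersion with exact boundaries", {
  res <- dispersion_statistic(c(2, 2, 2, 2), c(2, 2, 2, 2), n_params = 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$classification, "underdispersed")

  r <- gwgpr:::classify_dispersion(32, 32, "deviance")
  expect_equal(r$classification, "equidispersed")
  expect_equal(gwgpr:::classify_dispersion(32 * (1 + 1e-6), 32, "deviance")$classification,
               "overdispersed")
  expect_error(dispersion_statistic(1:3, c(1, 2, 3), n_params = 3), "degrees of freedom")
})

test_that("deviance and Pearson dispersion modes agree away from the boundary", {
  # equidispersed data: both ratios near 1 (classification at the boundary
  # is a coin flip between modes, so only the ratio is asserted)
  g <- generate_scenario(constant_scenario(n = 500, phi = 0, seed = 77L))
  pf <- fit_poisson(g$dataset)
  d1 <- dispersion_statistic(g$dataset$y, pf$fitted, 3, mode = "deviance")
  d2 <- dispersion_statistic(g$dataset$y, pf$fitted, 3, mode = "pearson")
  expect_lt(abs(d1$ratio - 1), 0.25)
  expect_lt(abs(d2$ratio - 1), 0.25)
  # clearly overdispersed data: both modes classify identically
  go <- generate_scenario(constant_scenario(n = 500, phi = 0.3, seed = 78L))
  po <- fit_poisson(go$dataset)
  o1 <- dispersion_statistic(go$dataset$y, po$fitted, 3, mode = "deviance")
  o2 <- dispersion_statistic(go$dataset$y, po$fitted, 3, mode = "pearson")
  expect_equal(o1$classification, "overdispersed")
  expect_equal(o2$classification, "overdispersed")
})

test_that("diagnose keeps BP size under the homogeneous equidispersed design", {
  fails <- 0L
  reps <- 40L
  for (s in seq_len(reps)) {
    g <- generate_scenario(constant_scenario(n = 150, phi = 0, seed = 5000L + s))
    d <- diagnose(g$dataset)
    fails <- fails + !d$bp$reject
  }
  expect_gte(fails / reps, 0.85)
})
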
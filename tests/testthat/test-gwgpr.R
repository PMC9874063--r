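test_that("local log-likelihood reduces to the global one under unit weights", {
  ds <- small_spatial_dataset(n = 40)
  beta <- c(0.8, 0.2, -0.1)
  phi <- 0.2
  A <- cbind(1, ds$X)
  global <- sum(gp_logpmf(ds$y, exp(drop(A %*% beta)), phi))
  expect_equal(local_loglik(beta, phi, ds, rep(1, ds$n)), global, tolerance = 1e-12)

  onehot <- rep(0, ds$n); onehot[5] <- 1
  # a one-hot row is infeasible for fitting but fine for evaluation checks
  expect_error(fit_local(ds, onehot), "positively weighted")

  set.seed(15)
  w <- runif(ds$n)
  brute <- sum(w * gp_logpmf(ds$y, exp(drop(A %*% beta)), phi))
  expect_equal(local_loglik(beta, phi, ds, w), brute, tolerance = 1e-12)
})

test_that("a unit-weight local fit equals the global GPR fit", {
  ds <- small_spatial_dataset(n = 50)
  lf <- fit_local(ds, rep(1, ds$n), location = 1)
  gf <- fit_gpr(ds)
  expect_lt(max(abs(lf$coefficients - coef(gf))), 1e-4)
  expect_lt(abs(lf$phi - gf$phi), 1e-4)
})

test_that("locality: observations with zero weight cannot influence a local fit", {
  ds <- small_spatial_dataset(n = 40)
  dm <- distance_matrix(ds)
  spec <- kernel_spec("fixed_bisquare", stats::median(dm))
  W <- weight_matrix(dm, spec, min_positive = ds$k + 2L)
  i <- 3L
  out <- which(W$w[i, ] == 0)
  expect_gt(length(out), 0)
  j <- out[1]
  y2 <- ds$y; y2[j] <- y2[j] + 40L
  ds2 <- spatial_count_dataset(y2, ds$X, ds$coords)
  f1 <- fit_local(ds, W$w[i, ], location = i)
  f2 <- fit_local(ds2, W$w[i, ], location = i)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$phi, f2$phi, tolerance = 1e-10)
})

test_that("all-zero counts in the weighted window do not crash the local fit", {
  set.seed(44)
  y <- c(rep(0L, 10), rpois(20, 3))
  X <- cbind(x1 = rnorm(30))
  coords <- cbind(c(seq(0, 0.09, length.out = 10), runif(20, 0.8, 1)),
                  rep(0, 30))
  ds <- spatial_count_dataset(y, X, coords)
  w <- as.numeric(coords[, 1] < 0.1)
  lf <- suppressWarnings(fit_local(ds, w, location = 1, max_iter = 30))
  expect_true(is.finite(lf$coefficients[2]) || !lf$converged)
  expect_lt(lf$coefficients[1], -2)  # intercept driven strongly negative
})

test_that("GWGPR returns one local fit per location in input order", {
  ds <- small_spatial_dataset(n = 36)
  fit <- fit_gwgpr(ds, kernel_spec("fixed_bisquare", 0.6))
  expect_length(fit$local, ds$n)
  expect_equal(vapply(fit$local, `[[`, integer(1), "location"), seq_len(ds$n))
  expect_equal(dim(fit$beta), c(ds$n, ds$k + 1L))
  expect_equal(fit$fitted,
               exp(rowSums(cbind(1, ds$X) * fit$beta)), tolerance = 1e-10)
})

test_that("near-infinite bandwidth collapses every local fit onto the global GPR", {
  ds <- small_spatial_dataset(n = 40)
  dmax <- max(distance_matrix(ds))
  fit <- fit_gwgpr(ds, kernel_spec("fixed_bisquare", 1e6 * dmax))
  gf <- fit_gpr(ds)
  expect_lt(max(abs(sweep(fit$beta, 2, coef(gf)))), 1e-3)
  expect_lt(max(abs(fit$phi - gf$phi)), 1e-3)
})

test_that("two-regime data: local estimates track the regional truth better than the global fit", {
  g <- generate_scenario(preset("heterogeneous_step"))
  idx <- seq_len(100)
  ds <- spatial_count_dataset(g$dataset$y[idx], g$dataset$X[idx, , drop = FALSE],
                              g$dataset$coords[idx, , drop = FALSE])
  truth1 <- g$truth$beta1[idx]
  fit <- fit_gwgpr(ds, kernel_spec("fixed_bisquare", 0.3))
  gf <- fit_gpr(ds)
  mae_local <- mean(abs(fit$beta[, 2] - truth1))
  mae_global <- mean(abs(coef(gf)[2] - truth1))
  expect_lt(mae_local, mae_global)
  # sign pattern of the step surface is recovered at most locations
  expect_gte(mean(sign(fit$beta[, 2]) == sign(truth1)), 0.9)
})

test_that("simultaneous and partial GWGPR tests follow their contracts", {
  ds <- small_spatial_dataset(n = 49)
  fit <- fit_gwgpr(ds, kernel_spec("fixed_bisquare", 0.4))
  st <- gwgpr_simultaneous_test(fit)
  expect_gte(st$statistic, 0)
  expect_equal(st$df, ds$k)
  # the published decision arithmetic: D = 180.9181 on 5 df exceeds 11.07
  expect_true(180.9181 > qchisq(0.95, 5))

  pt <- gwgpr_partial_tests(fit)
  expect_equal(nrow(pt), ds$n * (ds$k + 1L))
  exp_sig <- ifelse(pt$indeterminate, FALSE, abs(pt$z) > qnorm(0.975))
  expect_equal(pt$significant, exp_sig)
  # strict tie-break and zero-estimate behaviour
  fit2 <- fit
  fit2$beta[1, 2] <- 0
  fit2$se[1, 2] <- 1
  pt2 <- gwgpr_partial_tests(fit2)
  expect_false(pt2$significant[pt2$location == 1 & pt2$parameter == "x1"])
})

test_that("significance grouping partitions locations by identical variable sets", {
  base <- fit_gwgpr(small_spatial_dataset(n = 38), kernel_spec("fixed_bisquare", 0.5))
  # constructed pattern: sets of sizes 30 / 7 / 1
  sets <- c(rep(list(c("x1", "x2")), 30), rep(list("x1"), 7), list(character(0)))
  fake <- base
  fake$significant_sets <- sets
  fake$location_labels <- paste0("L", 1:38)
  groups <- significance_groups(fake)
  expect_length(groups, 3)
  expect_equal(vapply(groups, `[[`, integer(1), "size"), c(30L, 7L, 1L))
  expect_equal(groups[[1]]$variables, c("x1", "x2"))
  expect_equal(groups[[3]]$variables, character(0))  # empty set is a valid key
  expect_setequal(unlist(lapply(groups, `[[`, "indices")), 1:38)

  # all locations sharing one set collapse to a single group
  fake$significant_sets <- rep(list("x1"), 38)
  expect_length(significance_groups(fake), 1)
})

test_that("model AIC uses the stated parameter counts", {
  fake <- structure(list(aic = -2 * (-100) + 2 * 6), class = "gpr_fit")
  expect_equal(model_aic(fake), 212)
  ds <- small_spatial_dataset(n = 36)
  pf <- fit_poisson(ds); gf <- fit_gpr(ds)
  expect_equal(model_aic(pf), -2 * pf$loglik + 2 * (ds$k + 1))
  expect_equal(model_aic(gf), -2 * gf$loglik + 2 * (ds$k + 2))
})
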
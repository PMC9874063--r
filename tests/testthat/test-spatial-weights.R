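test_that("kernel weights match closed forms and have compact support", {
  expect_equal(kernel_weight(0, 2, "bisquare"), 1)
  expect_equal(kernel_weight(0, 2, "tricube"), 1)
  expect_equal(kernel_weight(1, 1, "bisquare"), 0)
  expect_equal(kernel_weight(2, 1, "tricube"), 0)
  expect_equal(kernel_weight(0.5, 1, "bisquare"), (3 / 4)^2)
  expect_equal(kernel_weight(0.5, 1, "tricube"), (7 / 8)^3)
  expect_error(kernel_weight(1, 0, "bisquare"), "positive")
})

test_that("kernel weights are non-increasing in distance and bounded in [0, 1]", {
  d <- seq(0, 2, by = 0.01)
  for (kind in c("bisquare", "tricube")) {
    w <- kernel_weight(d, 1, kind)
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w >= 0 & w <= 1))
    expect_true(all((w == 0) == (d >= 1)))   # vanishes iff d >= h
  }
})

test_that("adaptive bandwidths equal the sorted-distance oracle", {
  # 4 collinear points spaced 1 apart, N = 2
  dm <- distance_matrix(cbind(0:3, rep(0, 4)))
  h <- resolve_adaptive_bandwidths(dm, 2)
  expect_equal(h, c(2, 1, 1, 2))
  # the N-th neighbour sits exactly on the support boundary: weight 0.
  # interior points have BOTH neighbours tied at d = h, so only the
  # self-weight survives there (min_positive = 1 to observe it)
  W <- weight_matrix(dm, kernel_spec("adaptive_bisquare", 2), min_positive = 1)
  expect_equal(W$w[1, 3], 0)
  expect_gt(W$w[1, 2], 0)
  expect_equal(sum(W$w[2, ] > 0), 1L)

  set.seed(61)
  dm2 <- distance_matrix(cbind(runif(20), runif(20)))
  for (N in c(3, 10, 19)) {
    h2 <- resolve_adaptive_bandwidths(dm2, N)
    oracle <- sapply(1:20, function(i) sort(dm2[i, -i])[N])
    expect_equal(h2, oracle)
  }
  expect_equal(resolve_adaptive_bandwidths(dm2, 19),
               apply(dm2, 1, max))
  expect_error(resolve_adaptive_bandwidths(dm2, 20), "N must be")
})

test_that("weight matrix matches a brute-force double loop and flags infeasible rows", {
  set.seed(71)
  coords <- cbind(runif(15), runif(15))
  dm <- distance_matrix(coords)
  h <- 0.5
  W <- weight_matrix(dm, kernel_spec("fixed_tricube", h), min_positive = 2)
  brute <- matrix(0, 15, 15)
  for (i in 1:15) for (j in 1:15) {
    t <- dm[i, j] / h
    brute[i, j] <- if (t < 1) (1 - t^3)^3 else 0
  }
  expect_equal(W$w, brute, tolerance = 1e-14)
  expect_equal(diag(W$w), rep(1, 15))

  # bandwidth above the diameter: everything positive
  Wall <- weight_matrix(dm, kernel_spec("fixed_bisquare", 2 * max(dm)))
  expect_true(all(Wall$w > 0))
  # bandwidth below the smallest off-diagonal distance: infeasible
  hmin <- min(dm[dm > 0])
  expect_error(weight_matrix(dm, kernel_spec("fixed_bisquare", hmin * 0.9),
                             min_positive = 2),
               "row")
})

test_that("adaptive weight rows carry at least N - 1 positive neighbours", {
  set.seed(81)
  dm <- distance_matrix(cbind(runif(25), runif(25)))
  for (N in c(4, 9, 15)) {
    W <- weight_matrix(dm, kernel_spec("adaptive_bisquare", N), min_positive = 2)
    off <- rowSums(W$w > 0) - 1L
    expect_true(all(off >= N - 1))
  }
})

test_that("leave-one-out CV excludes the held-out observation", {
  ds <- small_spatial_dataset(n = 30)
  dm <- distance_matrix(ds)
  spec <- kernel_spec("fixed_bisquare", max(dm))
  W <- weight_matrix(dm, spec, min_positive = ds$k + 2L)
  i <- 7L
  w <- W$w[i, ]; w[i] <- 0
  base <- fit_local(ds, w, location = i)
  # perturb y_i: the leave-one-out prediction at i must not move
  y2 <- ds$y; y2[i] <- y2[i] + 25L
  ds2 <- spatial_count_dataset(y2, ds$X, ds$coords)
  pert <- fit_local(ds2, w, location = i)
  expect_equal(base$mu_i, pert$mu_i, tolerance = 1e-8)
  expect_gte(cv_score(ds, spec), 0)
})

test_that("CV at an effectively infinite bandwidth equals the global leave-one-out score", {
  ds <- small_spatial_dataset(n = 25)
  dm <- distance_matrix(ds)
  spec <- kernel_spec("fixed_bisquare", 1e6 * max(dm))
  cv <- cv_score(ds, spec, dm = dm)
  # oracle: global GPR refitted without observation i, every i
  A <- cbind(1, ds$X)
  total <- 0
  for (i in seq_len(ds$n)) {
    keep <- setdiff(seq_len(ds$n), i)
    eng <- gwgpr:::gpr_engine(ds$y[keep], A[keep, , drop = FALSE])
    total <- total + (ds$y[i] - exp(drop(A[i, ] %*% eng$beta)))^2
  }
  expect_equal(cv, total, tolerance = 1e-4 * total)
})

test_that("bandwidth search minimises CV over its trace and orders scenarios sensibly", {
  ds_het <- small_spatial_dataset(n = 49, preset_name = "heterogeneous_step")
  bw_het <- select_bandwidth(ds_het, "fixed_bisquare")
  expect_equal(bw_het$cv, min(bw_het$trace$cv))
  expect_true(all(bw_het$trace$cv >= bw_het$cv))

  g_const <- generate_scenario(constant_scenario(n = 49, phi = 0.3, seed = 404L))
  bw_const <- select_bandwidth(g_const$dataset, "fixed_bisquare")
  expect_equal(bw_const$cv, min(bw_const$trace$cv))
  # constant-coefficient data favour wide smoothing relative to two-regime data
  expect_lt(bw_het$bandwidth, bw_const$bandwidth)
})

test_that("adaptive search scans the full integer neighbour range", {
  ds <- small_spatial_dataset(n = 25)
  bw <- select_bandwidth(ds, "adaptive_bisquare")
  expect_setequal(bw$trace$bandwidth, seq(ds$k + 2, ds$n - 1))
  expect_equal(bw$cv, min(bw$trace$cv))
})
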
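# Shared fixture builders; all data are generated in code.

# small deterministic dataset for oracle comparisons (20 rows, 2 predictors)
fixed_dataset_20 <- function() {
  set.seed(2718)
  n <- 20L
  X <- cbind(x1 = round(runif(n, -1, 1), 3), x2 = round(rnorm(n), 3))
  coords <- cbind(round(runif(n), 3), round(runif(n), 3))
  eta <- 1 + 0.5 * X[, 1] - 0.4 * X[, 2]
  y <- rpois(n, exp(eta))
  spatial_count_dataset(y, X, coords)
}

# single-predictor generalized Poisson scenario used by recovery tests
gp_recovery_scenario <- function(n = 1000L, phi = 0.3, seed = 42L) {
  synthetic_scenario(n, list(gwgpr:::surface_constant(1.0),
                             gwgpr:::surface_constant(0.4)),
                     phi = phi, seed = seed)
}

constant_scenario <- function(n = 200L, phi = 0, seed = 101L) {
  synthetic_scenario(n, list(gwgpr:::surface_constant(1.0),
                             gwgpr:::surface_constant(0.4),
                             gwgpr:::surface_constant(-0.3)),
                     phi = phi, seed = seed)
}

# subsample of a preset, for fast GWGPR-scale tests
small_spatial_dataset <- function(n = 60L, preset_name = "heterogeneous_step") {
  g <- generate_scenario(preset(preset_name))
  idx <- seq_len(n)
  spatial_count_dataset(g$dataset$y[idx], g$dataset$X[idx, , drop = FALSE],
                        g$dataset$coords[idx, , drop = FALSE])
}
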
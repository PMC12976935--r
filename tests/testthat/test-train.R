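small_bm <- function(seed = 1, n_samples = 200, ...) {
  generate_benchmark(n_samples = n_samples, seed = seed, ...)
}

fast_cfg <- function(...) {
  defaults <- list(n_clusters = 3, hidden_layers = c(16, 16),
                   learning_rate = 1e-2, max_iters = 1500,
                   early_stop_patience = 300)
  do.call(funclust_config, utils::modifyList(defaults, list(...)))
}

test_that("split_data partitions deterministically", {
  X <- matrix(runif(100), nrow = 10)
  F_mat <- matrix(runif(10), ncol = 1)
  sp <- split_data(X, F_mat, 0.8, seed = 3)
  expect_equal(nrow(sp$X_train), 8)
  expect_equal(nrow(sp$X_test), 2)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:10)
  sp2 <- split_data(X, F_mat, 0.8, seed = 3)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(split_data(X[1:3, ], F_mat[1:3, , drop = FALSE], 0.8, 1),
               class = "funclust_bad_input")
})

test_that("the temperature schedule decays exponentially to its floor", {
  cfg <- funclust_config()
  expect_equal(anneal_tau(0, cfg), 1.0)
  expect_equal(anneal_tau(1e6, cfg), 0.1)
  steps <- seq(0, 5000, by = 50)
  taus <- anneal_tau(steps, cfg)
  expect_true(all(diff(taus) <= 0))

  flat <- funclust_config(tau_rate = 0)
  expect_equal(anneal_tau(1000, flat), flat$tau_max)
})

test_that("training reduces the held-out loss and is seed-deterministic", {
  bm <- small_bm()
  X <- as.matrix(bm$abundance[, -1]); F_mat <- as.matrix(bm$functions[, -1])
  cfg <- fast_cfg(seed = 4)
  sp <- split_data(X, F_mat, 0.8, seed = 10)

  init <- init_cluster_model(ncol(X), 1, cfg, seed = 20)
  initial_loss <- funclust:::heldout_mse(init, sp$X_test, sp$F_test)
  m1 <- train_member(sp, cfg, seed = 20)
  expect_lt(m1$test_loss, initial_loss)
  expect_lte(m1$test_r2, 1)

  m2 <- train_member(sp, cfg, seed = 20)
  expect_identical(m1$model$logits, m2$model$logits)
  expect_identical(m1$model$net$W, m2$model$net$W)
  expect_equal(m1$test_loss, m2$test_loss)
})

test_that("on a linear truth a trained member rivals the exact linear oracle", {
  co <- list(a1 = c(0.5, 1, -1), a2 = c(0.5, 1, -1), a3 = c(0.5, 1, -1))
  bm <- generate_benchmark(n_samples = 300, coefficients = co, seed = 6)
  X <- as.matrix(bm$abundance[, -1]); F_mat <- as.matrix(bm$functions[, -1])
  sp <- split_data(X, F_mat, 0.8, seed = 2)
  m <- train_member(sp, fast_cfg(seed = 5, max_iters = 2500), seed = 5)

  # closed-form oracle: OLS on the true group sums
  G_train <- group_sums(sp$X_train, bm$truth$true_group)
  G_test <- group_sums(sp$X_test, bm$truth$true_group)
  fit <- lm.fit(cbind(1, G_train), sp$F_train)
  pred <- cbind(1, G_test) %*% fit$coefficients
  oracle_r2 <- r_squared(sp$F_test, pred)

  expect_gt(m$test_r2, oracle_r2 - 0.05)
})

test_that("ensembles have distinct split seeds and are order-independent", {
  bm <- small_bm()
  cfg <- fast_cfg(seed = 11, n_ensemble = 3, max_iters = 400)
  ens <- train_ensemble(bm$abundance, bm$functions, cfg)
  expect_length(ens$members, 3)
  seeds <- vapply(ens$members, function(m) m$split_seed, numeric(1))
  expect_false(anyDuplicated(seeds) > 0)

  # rerunning reproduces every member exactly
  ens2 <- train_ensemble(bm$abundance, bm$functions, cfg)
  for (k in 1:3) {
    expect_identical(ens$members[[k]]$model$logits, ens2$members[[k]]$model$logits)
  }

  td <- tidy(ens)
  expect_equal(nrow(td), 3)
  expect_true(all(td$test_r2 <= 1))
  gl <- glance(ens)
  expect_equal(gl$n_members, 3)
})

test_that("grid search returns the argmin of its own results table", {
  bm <- small_bm(n_samples = 120)
  cfg <- fast_cfg(seed = 3, n_ensemble = 2, max_iters = 300)

  # singleton grids return the base configuration
  single <- grid_search(bm$abundance, bm$functions, cfg,
                        eta_grid = cfg$learning_rate,
                        tau_rate_grid = cfg$tau_rate)
  expect_equal(nrow(single$results), 1)
  expect_equal(single$best_config$learning_rate, cfg$learning_rate)

  gs <- grid_search(bm$abundance, bm$functions, cfg,
                    eta_grid = c(1e-3, 1e-2), tau_rate_grid = c(1e-3, 1e-2))
  expect_equal(nrow(gs$results), 4)
  best_row <- which.min(gs$results$median_test_loss)
  expect_equal(gs$best_config$learning_rate, gs$results$learning_rate[best_row])
  expect_equal(gs$best_config$tau_rate, gs$results$tau_rate[best_row])
})

test_that("the cluster-number scan reports the function variance as reference", {
  bm <- small_bm(n_samples = 120)
  cfg <- fast_cfg(seed = 7, n_ensemble = 2, max_iters = 300)
  scan <- scan_ncluster(bm$abundance, bm$functions, cfg, cluster_range = c(1, 3))
  expect_equal(nrow(scan$summary), 2)
  expect_equal(scan$reference_variance, var(bm$functions$f))
  expect_equal(nrow(scan$per_member), 4)
  # a single group cannot beat three on regime-switching data
  expect_gt(scan$summary$median_test_loss[scan$summary$n_clusters == 1],
            scan$summary$median_test_loss[scan$summary$n_clusters == 3])
})
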
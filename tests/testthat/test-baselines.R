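test_that("co-occurrence clustering groups perfectly correlated features and ignores the function", {
  set.seed(6)
  base <- matrix(runif(300), nrow = 100, ncol = 3)
  # three perfectly correlated pairs plus noise columns
  X <- cbind(base, base * 2)[, c(1, 4, 2, 5, 3, 6)]
  dimnames(X) <- list(paste0("s", 1:100), paste0("f", 1:6))
  f <- rowSums(base)
  ab <- funclust:::matrix_to_tibble(X)
  fn <- tibble::tibble(sample_id = rownames(X), f = f)

  res <- baseline_model_I(ab, fn, n_clusters = 3, split_seed = 1)
  g <- res$grouping$group
  expect_equal(g[1], g[2]); expect_equal(g[3], g[4]); expect_equal(g[5], g[6])

  # function-blindness: permuting F across samples leaves the grouping fixed
  fn_perm <- fn; fn_perm$f <- sample(fn$f)
  res2 <- baseline_model_I(ab, fn_perm, n_clusters = 3, split_seed = 1)
  expect_equal(res$grouping$group, res2$grouping$group)
})

test_that("model II shares model I's clustering but swaps in the neural map", {
  bm <- generate_benchmark(n_samples = 150, seed = 4)
  cfg <- funclust_config(n_clusters = 3, hidden_layers = c(8, 8),
                         learning_rate = 1e-2, max_iters = 600,
                         early_stop_patience = 200)
  r1 <- baseline_model_I(bm$abundance, bm$functions, 3, split_seed = 2)
  r2 <- baseline_model_II(bm$abundance, bm$functions, 3, split_seed = 2,
                          config = cfg)
  expect_equal(r1$grouping$group, r2$grouping$group)
  expect_equal(jaccard_index(bm$truth, r1$grouping)$total,
               jaccard_index(bm$truth, r2$grouping)$total)
  expect_true(is.finite(r2$test_r2))

  # richer map: at convergence the network's training MSE cannot exceed OLS's
  X <- as.matrix(bm$abundance[, -1]); F_mat <- as.matrix(bm$functions[, -1])
  sp <- split_data(X, F_mat, 0.8, 2)
  C <- funclust:::one_hot(funclust:::cooccurrence_clusters(X, 3), 3)
  net <- funclust:::fit_network(sp$X_train %*% C, sp$F_train,
                                sp$X_test %*% C, sp$F_test,
                                funclust_config(n_clusters = 3,
                                                hidden_layers = c(16, 16),
                                                learning_rate = 1e-2,
                                                max_iters = 3000,
                                                early_stop_patience = 1500),
                                seed = 3)
  ols_sse <- funclust:::ols_train_sse(sp$X_train %*% C, sp$F_train)
  pred_train <- funclust:::net_forward(net$net, sp$X_train %*% C, "tanh")
  expect_lte(sum((sp$F_train - pred_train)^2), ols_sse * 1.05)
})

test_that("model III recovers a linear truth and honours a zero move budget", {
  co <- list(a1 = c(2, -1, 0.5), a2 = c(2, -1, 0.5), a3 = c(2, -1, 0.5))
  bm <- generate_benchmark(n_samples = 200, coefficients = co, seed = 8)

  res <- baseline_model_III(bm$abundance, bm$functions, 3, split_seed = 1,
                            n_moves = 6000, n_restarts = 2, seed = 5)
  expect_gte(jaccard_index(bm$truth, res$grouping)$total, 0.9)
  expect_gt(res$test_r2, 0.95)

  # zero moves: the initial random assignment comes back unchanged
  res0a <- baseline_model_III(bm$abundance, bm$functions, 3, split_seed = 1,
                              n_moves = 0, n_restarts = 1, seed = 9)
  res0b <- baseline_model_III(bm$abundance, bm$functions, 3, split_seed = 1,
                              n_moves = 0, n_restarts = 1, seed = 9)
  expect_equal(res0a$grouping$group, res0b$grouping$group)
  expect_identical(res0a$grouping$group,
                   funclust:::with_seed(9, function() sample.int(3, 12, replace = TRUE)))
})

test_that("PCA + linear attains R2 = 1 on an exactly linear full-rank problem", {
  set.seed(12)
  X <- matrix(runif(200), nrow = 20, ncol = 10)
  colnames(X) <- paste0("f", 1:10)
  rownames(X) <- paste0("s", 1:20)
  beta <- rnorm(10)
  fn <- tibble::tibble(sample_id = rownames(X), f = as.numeric(X %*% beta))
  ab <- funclust:::matrix_to_tibble(X)

  res <- baseline_pca_linear(ab, fn, n_components = 10, split_seed = 2)
  expect_equal(res$test_r2, 1, tolerance = 1e-8)

  # train-split projections are uncorrelated
  sp <- split_data(X, as.matrix(fn[, -1]), 0.8, 2)
  pc <- prcomp(sp$X_train)
  proj <- pc$x[, 1:5]
  off_diag <- cor(proj)[upper.tri(diag(5))]
  expect_true(all(abs(off_diag) < 1e-8))
})

test_that("linear regression on true groups solves the linear benchmark", {
  co <- list(a1 = c(1, -2, 0.5), a2 = c(1, -2, 0.5), a3 = c(1, -2, 0.5))
  bm <- generate_benchmark(n_samples = 150, coefficients = co, seed = 10)
  truth_grouping <- tibble::tibble(feature_id = bm$truth$feature_id,
                                   group = bm$truth$true_group)
  res <- linear_on_groups(bm$abundance, bm$functions, truth_grouping,
                          split_seed = 3)
  expect_equal(res$test_r2, 1, tolerance = 1e-8)

  # a single all-encompassing group reduces to regression on total abundance
  one_group <- tibble::tibble(feature_id = bm$truth$feature_id, group = 1L)
  res1 <- linear_on_groups(bm$abundance, bm$functions, one_group, split_seed = 3)
  X <- as.matrix(bm$abundance[, -1])
  sp <- split_data(matrix(rowSums(X), ncol = 1), as.matrix(bm$functions[, -1]),
                   0.8, 3)
  pred <- cbind(1, sp$X_test) %*% lm.fit(cbind(1, sp$X_train), sp$F_train)$coefficients
  expect_equal(res1$test_r2, r_squared(sp$F_test, pred))

  # on the nonlinear benchmark the linear map on true groups is clearly worse
  bm_nl <- generate_benchmark(n_samples = 300, seed = 10)
  res_nl <- linear_on_groups(bm_nl$abundance, bm_nl$functions, truth_grouping,
                             split_seed = 3)
  expect_lt(res_nl$test_r2, 0.8)
})
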
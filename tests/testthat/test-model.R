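test_that("sampled clusterings are row-stochastic and sharpen as tau -> 0", {
  P <- matrix(c(0.98, 0.01, 0.01), nrow = 5, ncol = 3, byrow = TRUE)
  C <- sample_clustering(P, tau = 0.01, seed = 1)
  expect_equal(rowSums(C), rep(1, 5))
  expect_true(all(C[, 1] >= 0.99))

  # row sums are exactly 1 at any temperature
  set.seed(2)
  P2 <- funclust:::row_softmax(matrix(rnorm(30), 10, 3))
  for (tau in c(0.05, 0.5, 2)) {
    C2 <- sample_clustering(P2, tau = tau, seed = 3)
    expect_equal(rowSums(C2), rep(1, 10), tolerance = 1e-12)
  }

  expect_error(sample_clustering(P, tau = 0), class = "funclust_bad_input")
  # determinism given seed
  expect_identical(sample_clustering(P2, 0.1, seed = 7),
                   sample_clustering(P2, 0.1, seed = 7))
})

test_that("Gumbel-softmax argmax frequencies reproduce P (Gumbel-max property)", {
  P <- matrix(c(0.5, 0.3, 0.2), nrow = 1)
  n_draws <- 10000
  counts <- integer(3)
  set.seed(42)
  for (d in seq_len(n_draws)) {
    C <- sample_clustering(P, tau = 0.05)
    k <- which.max(C[1, ])
    counts[k] <- counts[k] + 1
  }
  freq <- counts / n_draws
  se <- sqrt(P[1, ] * (1 - P[1, ]) / n_draws)
  expect_true(all(abs(freq - P[1, ]) <= 3 * se))
})

test_that("the gate interpolates between closed and open", {
  x <- c(1, 2, 3)
  expect_equal(apply_gate(x, rep(20, 3)), x, tolerance = 1e-8)
  expect_equal(apply_gate(x, rep(-20, 3)), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply_gate(x, rep(0, 3)), x / 2)
  expect_error(apply_gate(x, rep(0, 2)), class = "funclust_bad_input")
})

test_that("group aggregation reproduces the worked 6-species example", {
  # hard clustering (1,2,1,1,3,2) of 6 species into 3 groups
  C <- funclust:::one_hot(c(1L, 2L, 1L, 1L, 3L, 2L), 3)
  expect_equal(group_abundances(rep(1, 6), C), c(3, 2, 1))

  # identity clustering returns the abundances unchanged
  expect_equal(group_abundances(c(2, 5, 7), diag(3)), c(2, 5, 7))

  # random abundances against a per-group summation loop
  set.seed(8)
  x <- runif(6)
  oracle <- sapply(1:3, function(g) sum(x[c(1, 2, 1, 1, 3, 2) == g]))
  expect_equal(group_abundances(x, C), oracle)
})

test_that("the network forward pass matches a hand computation", {
  cfg <- funclust_config(n_clusters = 2, hidden_layers = 2)
  model <- init_cluster_model(2, 1, cfg, seed = 1)
  # overwrite with hand-set weights: 1 hidden layer of 2 tanh units
  model$net$W <- list(matrix(c(1, 0, 0.5, -1), 2, 2), matrix(c(2, -1), 2, 1))
  model$net$b <- list(c(0.1, -0.2), 0.3)
  g <- c(0.4, 0.6)
  h <- tanh(c(0.4 * 1 + 0.6 * 0 + 0.1, 0.4 * 0.5 - 0.6 * 1 - 0.2))
  expect_equal(predict_function(g, model), sum(h * c(2, -1)) + 0.3)

  # zero final layer predicts 0 everywhere
  model$net$W[[2]][] <- 0; model$net$b[[2]][] <- 0
  expect_equal(predict_function(c(10, -3), model), 0)
  # determinism
  expect_identical(predict_function(g, model), predict_function(g, model))
})

test_that("the loss decomposes into MSE and gate penalty", {
  cfg <- funclust_config(n_clusters = 2, hidden_layers = 2, gate_strength = 1)
  model <- init_cluster_model(12, 1, cfg, seed = 1)
  # zero the network: predictions are 0
  model$net$W <- lapply(model$net$W, function(W) W * 0)
  X <- matrix(runif(24), nrow = 2)
  C <- funclust:::one_hot(rep(1:2, 6), 2)

  # hand-set residuals 1 and 2 with zero predictions: MSE = (1 + 4)/2
  F_mat <- matrix(c(-1, 2), ncol = 1)
  model$gate <- NULL
  expect_equal(model_loss(model, X, F_mat, C = C, beta = 0), 2.5)

  # wide-open gate over n = 12 features with beta = 1 adds exactly 12
  model$gate <- rep(1000, 12)
  expect_equal(model_loss(model, X, F_mat, C = C, beta = 1), 2.5 + 12)

  # perfect predictions give zero loss
  model$gate <- NULL
  expect_equal(model_loss(model, X, matrix(0, 2, 1), C = C), 0)
  expect_error(model_loss(model, X[0, , drop = FALSE], F_mat, C = C),
               class = "funclust_bad_input")
})

test_that("analytic gradients match finite differences", {
  set.seed(31)
  X <- matrix(runif(60), nrow = 10)
  F_mat <- matrix(rnorm(10), ncol = 1)
  cfg <- funclust_config(n_clusters = 3, hidden_layers = 8, gate_strength = 1e-3)
  model <- init_cluster_model(6, 1, cfg, seed = 5)
  gum <- funclust:::with_seed(9, function() funclust:::draw_gumbel(6, 3))
  lg <- funclust:::loss_and_grad(model, X, F_mat, tau = 0.3, beta = 1e-3,
                                 gumbel = gum)
  expect_equal(lg$loss,
               model_loss(model, X, F_mat, tau = 0.3, beta = 1e-3, gumbel = gum))

  eps <- 1e-6
  fd <- function(getter, setter) {
    p <- getter(model)
    g <- p * 0
    for (i in seq_along(p)) {
      up <- model_loss(setter(model, replace(p, i, p[i] + eps)), X, F_mat,
                       tau = 0.3, beta = 1e-3, gumbel = gum)
      dn <- model_loss(setter(model, replace(p, i, p[i] - eps)), X, F_mat,
                       tau = 0.3, beta = 1e-3, gumbel = gum)
      g[i] <- (up - dn) / (2 * eps)
    }
    g
  }
  rel_err <- function(num, ana) max(abs(num - ana)) / max(abs(num))

  num <- fd(function(m) m$logits,
            function(m, v) { m$logits <- matrix(v, nrow(m$logits)); m })
  expect_lt(rel_err(num, lg$grads$logits), 1e-4)

  num <- fd(function(m) m$gate, function(m, v) { m$gate <- v; m })
  expect_lt(rel_err(num, lg$grads$gate), 1e-4)

  for (j in 1:2) {
    num <- fd(function(m) m$net$W[[j]],
              function(m, v) { m$net$W[[j]] <- matrix(v, nrow(m$net$W[[j]])); m })
    expect_lt(rel_err(num, lg$grads$net$W[[j]]), 1e-4)
  }
})

test_that("the loss is invariant under a joint group relabelling", {
  set.seed(17)
  X <- matrix(runif(40), nrow = 5)
  F_mat <- matrix(rnorm(5), ncol = 1)
  cfg <- funclust_config(n_clusters = 3, hidden_layers = c(6, 6))
  model <- init_cluster_model(8, 1, cfg, seed = 2)
  model$logits <- matrix(rnorm(24), 8, 3)
  gum <- funclust:::with_seed(3, function() funclust:::draw_gumbel(8, 3))

  perm <- c(3, 1, 2)
  permuted <- model
  permuted$logits <- model$logits[, perm]
  permuted$net$W[[1]] <- model$net$W[[1]][perm, , drop = FALSE]
  expect_equal(
    model_loss(model, X, F_mat, tau = 0.2, gumbel = gum),
    model_loss(permuted, X, F_mat, tau = 0.2, gumbel = gum[, perm]))
})
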
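# Comparison models. Each one removes at least one ingredient of the full
# method (function-informed clustering, or the nonlinear map):
#   Model I   co-occurrence clustering + linear map
#   Model II  co-occurrence clustering + neural map
#   Model III Monte-Carlo function-informed clustering + linear map
#   PCA       principal-component projection + linear map
# All consume the same train/test split machinery as the main method so that
# comparisons can be paired on the split seed.

# Co-occurrence clustering: average-linkage hierarchical clustering on the
# correlation distance 1 - Pearson r, cut at K. Function-blind by
# construction. Constant features get zero correlation.
cooccurrence_clusters <- function(X, n_clusters) {
  cm <- suppressWarnings(cor(X))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  hc <- hclust(as.dist(1 - cm), method = "average")
  cutree(hc, k = n_clusters)
}

# OLS from group sums (plus intercept) to F on the train rows; returns the
# held-out predictions. Rank-deficient columns (e.g. empty groups) drop out
# with coefficient zero.
ols_group_predict <- function(G_train, F_train, G_test) {
  A <- cbind(1, G_train)
  fit <- lm.fit(A, F_train)
  beta <- as.matrix(fit$coefficients)
  beta[is.na(beta)] <- 0
  cbind(1, G_test) %*% beta
}

ols_train_sse <- function(G, F_mat) {
  fit <- lm.fit(cbind(1, G), F_mat)
  sum(as.matrix(fit$residuals)^2)
}

baseline_result <- function(assignment, feature_ids, r2, method) {
  grouping <- tibble::tibble(feature_id = feature_ids,
                             group = as.integer(assignment),
                             active = TRUE, agreement = 1)
  class(grouping) <- c("funclust_grouping", class(grouping))
  list(grouping = grouping, test_r2 = r2, method = method)
}

#' Baseline Model I: co-occurrence clustering + linear map
#'
#' Features are clustered from pairwise abundance correlations alone (the
#' function is never seen by the clustering); group sums are then regressed
#' linearly onto the function on the training split.
#'
#' @param abundance,functions Paired data (tibbles or matrices).
#' @param n_clusters Number of groups.
#' @param split_seed Seed for the train/test split.
#' @param train_fraction Training fraction (default 0.8).
#' @return A list with `grouping` (tibble), `test_r2`, `method`.
#' @export
baseline_model_I <- function(abundance, functions, n_clusters, split_seed = 1,
                             train_fraction = 0.8) {
  X <- as_sample_matrix(abundance, "abundance")
  F_mat <- as_sample_matrix(functions, "functions")
  assignment <- cooccurrence_clusters(X, n_clusters)
  split <- split_data(X, F_mat, train_fraction, split_seed)
  C <- one_hot(assignment, n_clusters)
  pred <- ols_group_predict(split$X_train %*% C, split$F_train, split$X_test %*% C)
  baseline_result(assignment, colnames(X), r_squared(split$F_test, pred),
                  "model_I")
}

#' Baseline Model II: co-occurrence clustering + neural map
#'
#' Same function-blind clustering as [baseline_model_I()], but the map from
#' group sums to function is the package's fully connected network, trained
#' with the clustering frozen.
#'
#' @inheritParams baseline_model_I
#' @param config A [funclust_config()] providing the network and optimizer
#'   settings (clustering-related fields are ignored).
#' @return A list with `grouping`, `test_r2`, `method`.
#' @export
baseline_model_II <- function(abundance, functions, n_clusters, split_seed = 1,
                              config = funclust_config(), train_fraction = 0.8) {
  X <- as_sample_matrix(abundance, "abundance")
  F_mat <- as_sample_matrix(functions, "functions")
  assignment <- cooccurrence_clusters(X, n_clusters)
  split <- split_data(X, F_mat, train_fraction, split_seed)
  C <- one_hot(assignment, n_clusters)
  fit <- fit_network(split$X_train %*% C, split$F_train,
                     split$X_test %*% C, split$F_test,
                     config, seed = split_seed)
  baseline_result(assignment, colnames(X), fit$test_r2, "model_II")
}

# Train only the structure-function network on fixed inputs G (no clustering
# parameters). Reuses the forward pass and layer gradients of the core model.
fit_network <- function(G_train, F_train, G_test, F_test, config, seed = 1) {
  widths <- c(ncol(G_train), config$hidden_layers, ncol(F_train))
  net <- with_seed(seed, function() {
    W <- list(); b <- list()
    for (j in seq_len(length(widths) - 1L)) {
      W[[j]] <- matrix(rnorm(widths[j] * widths[j + 1L],
                             sd = sqrt(2 / (widths[j] + widths[j + 1L]))),
                       nrow = widths[j])
      b[[j]] <- numeric(widths[j + 1L])
    }
    list(W = W, b = b)
  })
  act <- activation_fun(config$activation)
  flat <- list(); for (j in seq_along(net$W)) {
    flat[[paste0("W", j)]] <- net$W[[j]]; flat[[paste0("b", j)]] <- net$b[[j]]
  }
  state <- init_opt_state(flat)
  B <- nrow(G_train)
  best <- list(loss = Inf, flat = flat, iter = 0L)
  iter <- 0L
  while (iter < config$max_iters) {
    fw <- net_forward(net, G_train, config$activation, keep = TRUE)
    R <- fw$out - F_train
    dZ <- 2 * R / B
    grads <- list()
    for (j in rev(seq_along(net$W))) {
      grads[[paste0("W", j)]] <- crossprod(fw$As[[j]], dZ)
      grads[[paste0("b", j)]] <- colSums(dZ)
      if (j > 1L) {
        dZ <- (dZ %*% t(net$W[[j]])) * act$df(fw$Zs[[j - 1L]], fw$As[[j]])
      }
    }
    stepped <- opt_step(flat, grads, state, config)
    flat <- stepped$params; state <- stepped$state
    for (j in seq_along(net$W)) {
      net$W[[j]] <- flat[[paste0("W", j)]]; net$b[[j]] <- flat[[paste0("b", j)]]
    }
    iter <- iter + 1L
    if (iter %% config$eval_every == 0L || iter == config$max_iters) {
      test_loss <- sum((F_test - net_forward(net, G_test, config$activation))^2) /
        nrow(G_test)
      if (test_loss < best$loss - 1e-12) {
        best <- list(loss = test_loss, flat = flat, iter = iter)
      } else if (iter - best$iter >= config$early_stop_patience) break
    }
  }
  for (j in seq_along(net$W)) {
    net$W[[j]] <- best$flat[[paste0("W", j)]]
    net$b[[j]] <- best$flat[[paste0("b", j)]]
  }
  pred <- net_forward(net, G_test, config$activation)
  list(net = net, test_loss = best$loss, test_r2 = r_squared(F_test, pred))
}

#' Baseline Model III: Monte-Carlo function-informed clustering + linear map
#'
#' Simulated-annealing search over hard assignments (single-feature
#' reassignment moves, geometric temperature schedule, several restarts)
#' minimizing the training MSE of the best linear map from group sums to the
#' function. Function-informed, but restricted to a linear structure-function
#' map.
#'
#' @inheritParams baseline_model_I
#' @param n_moves Annealing moves per restart (default 20000).
#' @param n_restarts Independent restarts (default 5).
#' @param t_initial,t_final Geometric temperature schedule endpoints, as
#'   fractions of the initial objective scale.
#' @param seed Seed for the stochastic search.
#' @return A list with `grouping`, `test_r2`, `train_sse`, `method`.
#' @export
baseline_model_III <- function(abundance, functions, n_clusters, split_seed = 1,
                               n_moves = 20000, n_restarts = 5,
                               t_initial = 1, t_final = 1e-3,
                               train_fraction = 0.8, seed = split_seed) {
  X <- as_sample_matrix(abundance, "abundance")
  F_mat <- as_sample_matrix(functions, "functions")
  split <- split_data(X, F_mat, train_fraction, split_seed)
  n <- ncol(X); K <- n_clusters

  search_once <- function() {
    assignment <- sample.int(K, n, replace = TRUE)
    sse <- ols_train_sse(split$X_train %*% one_hot(assignment, K), split$F_train)
    best <- list(assignment = assignment, sse = sse)
    if (n_moves < 1) return(best)
    scale0 <- max(sse, .Machine$double.eps)
    cool <- (t_final / t_initial)^(1 / max(1, n_moves - 1))
    temp <- t_initial * scale0
    for (mv in seq_len(n_moves)) {
      i <- sample.int(n, 1)
      new_g <- sample.int(K - 1L, 1)
      new_g <- new_g + (new_g >= assignment[i])
      cand <- assignment; cand[i] <- new_g
      cand_sse <- ols_train_sse(split$X_train %*% one_hot(cand, K), split$F_train)
      if (cand_sse < sse || runif(1) < exp((sse - cand_sse) / temp)) {
        assignment <- cand; sse <- cand_sse
        if (sse < best$sse) best <- list(assignment = assignment, sse = sse)
      }
      temp <- temp * cool
    }
    best
  }

  best <- with_seed(seed, function() {
    runs <- lapply(seq_len(max(1, n_restarts)), function(r) search_once())
    runs[[which.min(vapply(runs, `[[`, numeric(1), "sse"))]]
  })

  C <- one_hot(best$assignment, K)
  pred <- ols_group_predict(split$X_train %*% C, split$F_train, split$X_test %*% C)
  out <- baseline_result(best$assignment, colnames(X),
                         r_squared(split$F_test, pred), "model_III")
  out$train_sse <- best$sse
  out
}

#' PCA + linear baseline
#'
#' Projects the abundance table onto its leading principal components
#' (computed on the training split) and regresses the function linearly on
#' the projections.
#'
#' @inheritParams baseline_model_I
#' @param n_components Number of principal components.
#' @return A list with `test_r2`, `method`, and the `rotation` used.
#' @export
baseline_pca_linear <- function(abundance, functions, n_components, split_seed = 1,
                                train_fraction = 0.8) {
  X <- as_sample_matrix(abundance, "abundance")
  F_mat <- as_sample_matrix(functions, "functions")
  split <- split_data(X, F_mat, train_fraction, split_seed)
  stopifnot(n_components <= min(dim(split$X_train)))
  pc <- prcomp(split$X_train, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  ctr <- pc$center
  proj <- function(M) sweep(M, 2, ctr) %*% rot
  pred <- ols_group_predict(proj(split$X_train), split$F_train, proj(split$X_test))
  list(test_r2 = r_squared(split$F_test, pred), method = "pca_linear",
       rotation = rot, n_components = n_components)
}

#' Linear regression on the group sums of a given grouping
#'
#' Measures how much predictive power a grouping retains when the
#' structure-function map is restricted to ordinary least squares.
#'
#' @inheritParams baseline_model_I
#' @param grouping A grouping tibble (`feature_id`, `group`, optionally
#'   `active`); inactive features are excluded from the sums.
#' @return A list with `test_r2` and `method`.
#' @export
linear_on_groups <- function(abundance, functions, grouping, split_seed = 1,
                             train_fraction = 0.8) {
  X <- as_sample_matrix(abundance, "abundance")
  F_mat <- as_sample_matrix(functions, "functions")
  assignment <- grouping$group[match(colnames(X), grouping$feature_id)]
  if ("active" %in% names(grouping)) {
    assignment[!grouping$active[match(colnames(X), grouping$feature_id)]] <- 0L
  }
  groups <- sort(unique(assignment[assignment > 0]))
  Gs <- vapply(groups, function(g) rowSums(X[, assignment == g, drop = FALSE]),
               numeric(nrow(X)))
  split <- split_data(matrix(Gs, nrow = nrow(X)), F_mat, train_fraction, split_seed)
  pred <- ols_group_predict(split$X_train, split$F_train, split$X_test)
  list(test_r2 = r_squared(split$F_test, pred), method = "linear_on_groups")
}
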
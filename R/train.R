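# Ensemble training: random train/test splits, full-batch first-order
# optimization of the joint clustering + network loss, exponential temperature
# annealing, early stopping on the held-out MSE.

#' Split paired data into train and test sets
#'
#' Draws `round(train_fraction * N)` samples uniformly at random for training;
#' the rest form the test set. The split is deterministic given `seed`.
#'
#' @param X N-by-n abundance matrix.
#' @param F_mat N-by-m function matrix (row-aligned with `X`).
#' @param train_fraction Fraction of samples for training.
#' @param seed Integer seed.
#' @return A list with `X_train`, `F_train`, `X_test`, `F_test`,
#'   `train_idx`, `test_idx`.
#' @export
split_data <- function(X, F_mat, train_fraction = 0.8, seed = 1) {
  N <- nrow(X)
  if (N < 5) abort("need at least 5 samples to split", class = "funclust_bad_input")
  n_train <- round(train_fraction * N)
  if (n_train < 1 || n_train >= N) {
    abort("train_fraction leaves an empty train or test set",
          class = "funclust_bad_input")
  }
  idx <- with_seed(seed, function() sort(sample.int(N, n_train)))
  list(
    X_train = X[idx, , drop = FALSE], F_train = F_mat[idx, , drop = FALSE],
    X_test = X[-idx, , drop = FALSE], F_test = F_mat[-idx, , drop = FALSE],
    train_idx = idx, test_idx = setdiff(seq_len(N), idx)
  )
}

#' Annealed Gumbel-softmax temperature
#'
#' \eqn{\tau(t) = \max(\tau_{min}, \tau_{max} e^{-r_\tau t})}: exponential
#' decay from `tau_max` to the floor `tau_min`, non-increasing in the
#' iteration index.
#'
#' @param step Iteration index (0-based).
#' @param config A [funclust_config()].
#' @return The temperature at `step`.
#' @export
anneal_tau <- function(step, config) {
  pmax(config$tau_min, config$tau_max * exp(-config$tau_rate * step))
}

# ---- Adam / SGD over the flat parameter list -------------------------------

flatten_params <- function(model) {
  out <- list(logits = model$logits)
  for (j in seq_along(model$net$W)) {
    out[[paste0("W", j)]] <- model$net$W[[j]]
    out[[paste0("b", j)]] <- model$net$b[[j]]
  }
  if (!is.null(model$gate)) out$gate <- model$gate
  out
}

flatten_grads <- function(grads, model) {
  out <- list(logits = grads$logits)
  for (j in seq_along(model$net$W)) {
    out[[paste0("W", j)]] <- grads$net$W[[j]]
    out[[paste0("b", j)]] <- grads$net$b[[j]]
  }
  if (!is.null(model$gate)) out$gate <- grads$gate
  out
}

unflatten_params <- function(flat, model) {
  model$logits <- flat$logits
  for (j in seq_along(model$net$W)) {
    model$net$W[[j]] <- flat[[paste0("W", j)]]
    model$net$b[[j]] <- flat[[paste0("b", j)]]
  }
  if (!is.null(model$gate)) model$gate <- flat$gate
  model
}

init_opt_state <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

opt_step <- function(flat, grads, state, config) {
  step_size <- function(nm) {
    if (nm == "logits" && !is.null(config$logit_learning_rate)) {
      config$logit_learning_rate
    } else {
      config$learning_rate
    }
  }
  if (config$optimizer == "sgd") {
    for (nm in names(flat)) flat[[nm]] <- flat[[nm]] - step_size(nm) * grads[[nm]]
    return(list(params = flat, state = state))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    flat[[nm]] <- flat[[nm]] -
      step_size(nm) * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = flat, state = state)
}

# Held-out MSE with the deterministic argmax clustering (no Gumbel noise, no
# gate penalty): the quantity watched by early stopping.
heldout_mse <- function(model, X, F_mat) {
  C <- one_hot(hard_assignment(model), ncol(model$logits))
  Xg <- if (!is.null(model$gate)) apply_gate(X, model$gate) else X
  pred <- net_forward(model$net, Xg %*% C, model$activation)
  sum((F_mat - pred)^2) / nrow(X)
}

#' Train one ensemble member
#'
#' Full-batch gradient optimization of the joint loss with per-iteration
#' temperature annealing. Every `eval_every` iterations the held-out MSE
#' (deterministic argmax clustering) is evaluated; training stops when it has
#' not improved for `early_stop_patience` iterations or at `max_iters`, and
#' the best-scoring parameters are restored.
#'
#' @param split A list as returned by [split_data()].
#' @param config A [funclust_config()].
#' @param seed Seed for initialization and Gumbel draws.
#' @return An object of class `trained_member`: the final `model`, `test_loss`
#'   (held-out MSE), `test_r2`, `train_loss`, `iterations_run`, `seed`.
#' @export
train_member <- function(split, config, seed = config$seed) {
  model <- init_cluster_model(ncol(split$X_train), ncol(split$F_train),
                              config, seed = seed)
  flat <- flatten_params(model)
  state <- init_opt_state(flat)
  beta <- config$gate_strength

  best_loss <- Inf
  best_flat <- flat
  best_iter <- 0L
  n <- ncol(split$X_train); K <- config$n_clusters

  old_rng <- get_rng_state()
  on.exit(restore_rng_state(old_rng))
  set.seed(seed + 1L)

  iter <- 0L
  while (iter < config$max_iters) {
    tau <- anneal_tau(iter, config)
    gumbel <- draw_gumbel(n, K)
    lg <- loss_and_grad(model, split$X_train, split$F_train, tau, beta, gumbel)
    if (!is.finite(lg$loss)) {
      abort(sprintf("non-finite training loss at iteration %d", iter),
            class = "funclust_nonfinite_loss")
    }
    stepped <- opt_step(flat, flatten_grads(lg$grads, model), state, config)
    flat <- stepped$params; state <- stepped$state
    model <- unflatten_params(flat, model)
    iter <- iter + 1L

    if (iter %% config$eval_every == 0L || iter == config$max_iters) {
      test_loss <- heldout_mse(model, split$X_test, split$F_test)
      if (test_loss < best_loss - 1e-12) {
        best_loss <- test_loss
        best_flat <- flat
        best_iter <- iter
      } else if (iter - best_iter >= config$early_stop_patience) {
        break
      }
    }
  }

  model <- unflatten_params(best_flat, model)
  C <- one_hot(hard_assignment(model), K)
  Xg_test <- if (!is.null(model$gate)) apply_gate(split$X_test, model$gate) else split$X_test
  pred_test <- net_forward(model$net, Xg_test %*% C, model$activation)

  structure(list(
    model = model,
    test_loss = best_loss,
    test_r2 = r_squared(split$F_test, pred_test),
    train_loss = heldout_mse(model, split$X_train, split$F_train),
    iterations_run = iter,
    seed = seed,
    split_idx = split$train_idx
  ), class = "trained_member")
}

# Standardize function columns; returns matrix plus the transform.
standardize_F <- function(F_mat, mode) {
  do_it <- isTRUE(mode) || (identical(mode, "auto") && ncol(F_mat) > 1)
  if (!do_it) {
    return(list(F_mat = F_mat, center = rep(0, ncol(F_mat)),
                scale = rep(1, ncol(F_mat))))
  }
  ctr <- colMeans(F_mat)
  scl <- apply(F_mat, 2, sd)
  scl[scl == 0] <- 1
  list(F_mat = sweep(sweep(F_mat, 2, ctr), 2, scl, `/`), center = ctr, scale = scl)
}

#' Train an ensemble of models
#'
#' Trains `config$n_ensemble` members, each on its own random train/test
#' split; split and initialization seeds are derived deterministically from
#' `config$seed`, and members are independent of training order.
#'
#' @param abundance Abundance tibble (first column `sample_id`) or numeric
#'   matrix.
#' @param functions Function tibble or numeric matrix, row-aligned (use
#'   [pair_samples()] first if needed).
#' @param config A [funclust_config()].
#' @return An object of class `funclust_ensemble` with `members`, `config`,
#'   the data matrices, and feature/function names.
#' @export
train_ensemble <- function(abundance, functions, config = funclust_config()) {
  X <- as_sample_matrix(abundance, "abundance")
  F_raw <- as_sample_matrix(functions, "functions")
  stopifnot(nrow(X) == nrow(F_raw))
  std <- standardize_F(F_raw, config$standardize_function)

  seeds <- derive_seeds(config$seed, 2L * config$n_ensemble)
  split_seeds <- seeds[seq_len(config$n_ensemble)]
  init_seeds <- seeds[config$n_ensemble + seq_len(config$n_ensemble)]

  members <- purrr::map(seq_len(config$n_ensemble), function(mu) {
    split <- split_data(X, std$F_mat, config$train_fraction, split_seeds[mu])
    m <- train_member(split, config, seed = init_seeds[mu])
    m$split_seed <- split_seeds[mu]
    m
  })

  structure(list(
    members = members,
    config = config,
    X = X,
    F_mat = std$F_mat,
    f_center = std$center,
    f_scale = std$scale,
    feature_ids = colnames(X),
    function_names = colnames(F_raw)
  ), class = "funclust_ensemble")
}

#' @export
print.funclust_ensemble <- function(x, ...) {
  r2 <- vapply(x$members, function(m) m$test_r2, numeric(1))
  cat(sprintf(
    "<funclust_ensemble> %d members, %d features -> %d groups; held-out R2 median %.3f (range %.3f..%.3f)\n",
    length(x$members), length(x$feature_ids), x$config$n_clusters,
    median(r2), min(r2), max(r2)))
  invisible(x)
}

#' Hyperparameter grid search
#'
#' Trains a full ensemble at every grid point over the learning rate, the
#' annealing rate, and (when gating) the sparsity strength, and returns the
#' configuration with the lowest median held-out MSE together with the full
#' results table.
#'
#' @param abundance,functions Paired data (tibbles or matrices).
#' @param config Base [funclust_config()].
#' @param eta_grid,tau_rate_grid,beta_grid Numeric grids; singletons keep the
#'   base value. `beta_grid` is only meaningful when gating is enabled.
#' @return A list with `best_config`, `results` (a tibble with one row per
#'   grid point: the grid values, median test loss and median test R2), and
#'   `best_ensemble`.
#' @export
grid_search <- function(abundance, functions, config = funclust_config(),
                        eta_grid = c(1e-3, 3e-3, 1e-2),
                        tau_rate_grid = c(1e-4, 1e-3, 1e-2),
                        beta_grid = NULL) {
  if (is.null(beta_grid)) beta_grid <- config$gate_strength
  grid <- expand.grid(learning_rate = eta_grid, tau_rate = tau_rate_grid,
                      gate_strength = beta_grid, KEEP.OUT.ATTRS = FALSE)
  fits <- purrr::pmap(grid, function(learning_rate, tau_rate, gate_strength) {
    cfg <- config
    cfg$learning_rate <- learning_rate
    cfg$tau_rate <- tau_rate
    cfg$gate_strength <- gate_strength
    ens <- train_ensemble(abundance, functions, cfg)
    losses <- vapply(ens$members, function(m) m$test_loss, numeric(1))
    r2 <- vapply(ens$members, function(m) m$test_r2, numeric(1))
    list(ensemble = ens, median_test_loss = median(losses),
         median_test_r2 = median(r2))
  })
  results <- tibble::as_tibble(grid) |>
    dplyr::mutate(
      median_test_loss = vapply(fits, `[[`, numeric(1), "median_test_loss"),
      median_test_r2 = vapply(fits, `[[`, numeric(1), "median_test_r2"))
  best <- which.min(results$median_test_loss)
  list(best_config = fits[[best]]$ensemble$config,
       results = results,
       best_ensemble = fits[[best]]$ensemble)
}

#' Scan the number of groups
#'
#' Trains one ensemble per candidate group number and summarizes the held-out
#' losses; the empirical variance of the (standardized) function values serves
#' as the reference level that a structureless predictor would attain.
#'
#' @param abundance,functions Paired data.
#' @param config Base [funclust_config()].
#' @param cluster_range Integer vector of group numbers to scan.
#' @return An object of class `funclust_scan`: a list with `summary` (tibble:
#'   `n_clusters`, `median_test_loss`, `min_test_loss`), `per_member` (tibble),
#'   and `reference_variance`.
#' @export
scan_ncluster <- function(abundance, functions, config = funclust_config(),
                          cluster_range = 2:6) {
  stopifnot(length(cluster_range) >= 1)
  per_member <- purrr::map_dfr(cluster_range, function(K) {
    cfg <- config
    # K = 1 (everything in one group) is allowed here as the degenerate
    # reference point of the scan, even though it is below the configurable
    # minimum for a standalone run.
    cfg$n_clusters <- as.integer(K)
    ens <- train_ensemble(abundance, functions, cfg)
    tibble::tibble(
      n_clusters = as.integer(K),
      member = seq_along(ens$members),
      test_loss = vapply(ens$members, function(m) m$test_loss, numeric(1)),
      test_r2 = vapply(ens$members, function(m) m$test_r2, numeric(1)))
  })
  F_raw <- as_sample_matrix(functions, "functions")
  std <- standardize_F(F_raw, config$standardize_function)
  ref_var <- sum(apply(std$F_mat, 2, var))
  summary <- per_member |>
    dplyr::group_by(.data$n_clusters) |>
    dplyr::summarise(median_test_loss = median(.data$test_loss),
                     min_test_loss = min(.data$test_loss), .groups = "drop")
  structure(list(summary = summary, per_member = per_member,
                 reference_variance = ref_var),
            class = "funclust_scan")
}

#' @export
print.funclust_scan <- function(x, ...) {
  cat("<funclust_scan> median held-out loss by group number\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat(sprintf("reference variance of f: %.4f\n", x$reference_variance))
  invisible(x)
}
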
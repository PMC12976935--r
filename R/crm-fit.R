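# Parameter inference for the consumer-resource model.
#
# Global yields (gamma1, gamma2) are shared across samples and found by grid
# search (optionally followed by a continuous local refinement); for every
# candidate yield pair, each sample's (r1, r2, t_star) is found by
# derivative-free local optimization of a weighted least-squares objective on
# the nitrate time series and the endpoint biomasses, using the
# piecewise-analytic solution. rC is fixed (default 1) and KA = KC = 1e-3; the
# results are insensitive to these.

#' Fitting configuration for [fit_crm()]
#'
#' @param gamma_grid_points Points per yield axis of the log-spaced grid
#'   (default 20).
#' @param gamma_range Range of the yield grid (1/mM, default `c(0.05, 5)`).
#' @param n_restarts Random restarts of the per-sample optimizer (default 5).
#' @param maxit Iteration cap per Nelder-Mead run (default 400).
#' @param refine_global Continue from the best grid point with a continuous
#'   local optimization of the yields (default `TRUE`).
#' @param refine_maxit Outer iteration cap for that refinement (default 60).
#' @param reltol Relative convergence tolerance of the inner Nelder-Mead
#'   runs (default 1e-8).
#' @param rC Fixed carbon-rate ratio (default 1).
#' @param KA,KC Fixed Monod affinities (default 1e-3 mM).
#' @param gamma_fixed Optional length-2 vector `c(gamma1, gamma2)`: skip the
#'   yield search entirely and fit only the per-sample parameters at these
#'   yields. Use when the global yields are already established (they are
#'   shared across all conditions, so in practice they come from one fit to
#'   a large dataset, after which per-sample rates are estimated at known
#'   yields).
#' @return A list of class `crm_fit_config`.
#' @export
crm_fit_config <- function(gamma_grid_points = 20, gamma_range = c(0.05, 5),
                           n_restarts = 5, maxit = 400, refine_global = TRUE,
                           refine_maxit = 60, reltol = 1e-8,
                           rC = 1, KA = 1e-3, KC = 1e-3, gamma_fixed = NULL) {
  structure(list(gamma_grid_points = as.integer(gamma_grid_points),
                 gamma_range = gamma_range, n_restarts = as.integer(n_restarts),
                 maxit = as.integer(maxit), refine_global = refine_global,
                 refine_maxit = as.integer(refine_maxit), reltol = reltol,
                 rC = rC, KA = KA, KC = KC, gamma_fixed = gamma_fixed),
            class = "crm_fit_config")
}

# Parse an observations tibble into the pieces the fit needs.
parse_crm_observations <- function(observations, times = NULL) {
  need <- c("sample_id", "x1_0", "x2_0", "x1_T", "x2_T")
  stopifnot(all(need %in% names(observations)))
  a_cols <- grep("^A_", names(observations), value = TRUE)
  stopifnot(length(a_cols) >= 3)
  if (is.null(times)) times <- as.numeric(sub("^A_", "", a_cols))
  stopifnot(!any(is.na(times)), all(diff(times) > 0))
  list(
    sample_id = as.character(observations$sample_id),
    x1_0 = observations$x1_0, x2_0 = observations$x2_0,
    x1_T = observations$x1_T, x2_T = observations$x2_T,
    A = as.matrix(observations[, a_cols]),
    times = times
  )
}

# Weighted objective for one sample at fixed yields. Parameters are
# unconstrained: r_i = exp(u_i), t_star = T * sigmoid(u_3). The nitrate block
# is normalized by the series variance; endpoints enter as per-endpoint
# relative errors so that the smaller biomass's constraint is not drowned by
# the larger one's scale.
sample_objective <- function(u, gamma1, gamma2, obs_s, times, weights, rC) {
  r1 <- exp(u[1]); r2 <- exp(u[2])
  t_star <- max(times) * sigmoid(u[3])
  pars <- list(gamma1 = gamma1, gamma2 = gamma2, r1 = r1, r2 = r2, rC = rC)
  traj <- analytic_nitrate_endpoints(pars, obs_s$x1_0, obs_s$x2_0, obs_s$A0,
                                     t_star, times)
  sse_A <- sum((traj$A - obs_s$A)^2)
  rel_sq <- function(pred, obs) if (obs > 0) (pred / obs - 1)^2 else pred^2
  sse_x <- rel_sq(traj$x1_T, obs_s$x1_T) + rel_sq(traj$x2_T, obs_s$x2_T)
  obj <- sse_A / weights$A + sse_x
  # overflow guard: extreme yield/rate combinations overflow the exponentials
  if (!is.finite(obj)) return(1e12)
  obj
}

# Lean analytic evaluation: nitrate at the observation times plus endpoint
# biomasses (avoids tibble overhead inside the optimizer).
analytic_nitrate_endpoints <- function(pars, x1_0, x2_0, A0, t_star, times) {
  g1r1 <- pars$gamma1 * pars$r1
  g2r2 <- pars$gamma2 * pars$r2
  T_end <- max(times)
  t_rep <- pmin(times, t_star)
  A <- A0 -
    replete_consumption(pars$r1, pars$gamma1, x1_0, t_rep) -
    replete_consumption(pars$r2, pars$gamma2, x2_0, t_rep)
  late <- times > t_star
  if (any(late)) {
    x1_star <- x1_0 * exp(g1r1 * t_star)
    x2_star <- x2_0 * exp(g2r2 * t_star)
    A_star <- A0 -
      replete_consumption(pars$r1, pars$gamma1, x1_0, t_star) -
      replete_consumption(pars$r2, pars$gamma2, x2_0, t_star)
    A[late] <- A_star - (pars$r1 * x1_star + pars$r2 * x2_star) *
      (times[late] - t_star)
  }
  t_grow <- min(t_star, T_end)
  list(A = pmax(A, 0),
       x1_T = x1_0 * exp(g1r1 * t_grow),
       x2_T = x2_0 * exp(g2r2 * t_grow))
}

# Heuristic start for one sample: t* from the point of strongest curvature
# of the nitrate series, rates from the endpoint growth ratios
# r_i = log(x_i(T)/x_i(0)) / (gamma_i t*).
heuristic_start <- function(gamma1, gamma2, obs_s, times) {
  T_end <- max(times)
  curv <- -diff(diff(obs_s$A))
  t_star0 <- if (length(curv) >= 1) times[which.max(curv) + 1L] else T_end / 2
  t_star0 <- min(max(t_star0, 0.05 * T_end), 0.95 * T_end)
  growth1 <- max(log(max(obs_s$x1_T, 1e-12) / max(obs_s$x1_0, 1e-12)), 1e-3)
  growth2 <- max(log(max(obs_s$x2_T, 1e-12) / max(obs_s$x2_0, 1e-12)), 1e-3)
  c(log(max(growth1 / (gamma1 * t_star0), 1e-3)),
    log(max(growth2 / (gamma2 * t_star0), 1e-3)),
    log(t_star0 / (T_end - t_star0)))
}

# Fit (r1, r2, t_star) for every sample at fixed yields; returns total
# objective and per-sample results. Starting points: a data-driven heuristic,
# an optional warm start from a previous solve, and seeded random restarts,
# so the whole fit is deterministic.
fit_samples_at_gamma <- function(gamma1, gamma2, parsed, config, starts,
                                 warm = NULL) {
  n_s <- length(parsed$sample_id)
  per_sample <- vector("list", n_s)
  u_mat <- matrix(NA_real_, n_s, 3)
  total <- 0
  for (s in seq_len(n_s)) {
    obs_s <- list(x1_0 = parsed$x1_0[s], x2_0 = parsed$x2_0[s],
                  x1_T = parsed$x1_T[s], x2_T = parsed$x2_T[s],
                  A = parsed$A[s, ], A0 = parsed$A[s, 1])
    degenerate2 <- obs_s$x2_0 == 0
    weights <- list(A = max(var(obs_s$A), 1e-12))
    u_starts <- rbind(heuristic_start(gamma1, gamma2, obs_s, parsed$times),
                      if (!is.null(warm)) warm[s, ],
                      starts[seq_len(max(0L, config$n_restarts - 1L)), ,
                             drop = FALSE])
    best <- NULL
    for (r in seq_len(nrow(u_starts))) {
      opt <- optim(u_starts[r, ], sample_objective, gamma1 = gamma1,
                   gamma2 = gamma2, obs_s = obs_s, times = parsed$times,
                   weights = weights, rC = config$rC, method = "Nelder-Mead",
                   control = list(maxit = config$maxit,
                                  reltol = config$reltol %||% 1e-8))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    u <- best$par
    u_mat[s, ] <- u
    per_sample[[s]] <- list(
      r1 = exp(u[1]),
      r2 = if (degenerate2) NA_real_ else exp(u[2]),
      t_star = max(parsed$times) * sigmoid(u[3]),
      objective = best$value)
    total <- total + best$value
  }
  list(total = total, per_sample = per_sample, u = u_mat)
}

#' Fit the consumer-resource model to per-sample observations
#'
#' Observations per sample: initial and final group biomasses and a nitrate
#' time series. Yields are global; rates and the carbon depletion time vary
#' per sample. Replicate rows sharing a `sample_id` prefix are not averaged
#' here; average replicates beforehand if desired.
#'
#' @param observations Tibble with columns `sample_id`, `x1_0`, `x2_0`,
#'   `x1_T`, `x2_T`, and nitrate columns named `A_<time>` (e.g. `A_0`,
#'   `A_0.444`, ...). The first nitrate column is taken as A(0).
#' @param config A [crm_fit_config()].
#' @param seed Seed for the optimizer's random restarts.
#' @return An object of class `crm_fit`: `gamma1`, `gamma2`,
#'   `per_sample` (tibble: `sample_id`, `r1`, `r2`, `t_star`, `objective`,
#'   `nitrate_mse`, `biomass1_sq_error`, `biomass2_sq_error`), `grid`
#'   (tibble of the yield grid with total objectives), `trajectories`
#'   (predicted `crm_trajectory` per sample), `config`.
#' @details If `x2_0` is zero for every sample the second biomass never
#'   enters the dynamics: `r2` is unidentifiable and reported as `NA`.
#' @export
fit_crm <- function(observations, config = crm_fit_config(), seed = 1) {
  parsed <- parse_crm_observations(observations)
  if (all(parsed$x1_0 == 0) && all(parsed$x2_0 == 0)) {
    abort("all-zero initial biomasses: no feasible parameters",
          class = "funclust_infeasible")
  }
  if (!is.null(config$gamma_fixed)) {
    stopifnot(length(config$gamma_fixed) == 2, all(config$gamma_fixed > 0))
    grid_vals <- NULL
  } else {
    grid_vals <- exp(seq(log(config$gamma_range[1]), log(config$gamma_range[2]),
                         length.out = config$gamma_grid_points))
  }
  starts <- with_seed(seed, function() {
    n <- max(1L, config$n_restarts)
    cbind(runif(n, log(0.05), log(2)), runif(n, log(0.05), log(2)),
          runif(n, -2, 2))
  })

  grid <- if (is.null(grid_vals)) {
    data.frame(gamma1 = config$gamma_fixed[1], gamma2 = config$gamma_fixed[2])
  } else {
    expand.grid(gamma1 = grid_vals, gamma2 = grid_vals, KEEP.OUT.ATTRS = FALSE)
  }
  totals <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- fit_samples_at_gamma(grid$gamma1[i], grid$gamma2[i],
                                      parsed, config, starts)
    totals[i] <- fits[[i]]$total
  }
  best_i <- which.min(totals)
  gamma1 <- grid$gamma1[best_i]; gamma2 <- grid$gamma2[best_i]
  best_fit <- fits[[best_i]]

  if (isTRUE(config$refine_global) && is.null(config$gamma_fixed)) {
    warm_env <- new.env()
    warm_env$u <- best_fit$u
    refined <- optim(log(c(gamma1, gamma2)), function(lg) {
      fit <- fit_samples_at_gamma(exp(lg[1]), exp(lg[2]), parsed, config,
                                  starts, warm = warm_env$u)
      warm_env$u <- fit$u
      fit$total
    }, method = "Nelder-Mead",
    control = list(maxit = config$refine_maxit %||% 60L))
    if (refined$value < best_fit$total) {
      gamma1 <- exp(refined$par[1]); gamma2 <- exp(refined$par[2])
      best_fit <- fit_samples_at_gamma(gamma1, gamma2, parsed, config, starts,
                                       warm = warm_env$u)
    }
  }

  n_s <- length(parsed$sample_id)
  per_sample <- tibble::tibble(
    sample_id = parsed$sample_id,
    r1 = vapply(best_fit$per_sample, `[[`, numeric(1), "r1"),
    r2 = vapply(best_fit$per_sample, `[[`, numeric(1), "r2"),
    t_star = vapply(best_fit$per_sample, `[[`, numeric(1), "t_star"),
    objective = vapply(best_fit$per_sample, `[[`, numeric(1), "objective"))

  trajectories <- vector("list", n_s)
  nitrate_mse <- numeric(n_s); b1_err <- numeric(n_s); b2_err <- numeric(n_s)
  for (s in seq_len(n_s)) {
    pars <- crm_parameters(gamma1, gamma2, per_sample$r1[s],
                           ifelse(is.na(per_sample$r2[s]), 0, per_sample$r2[s]),
                           rC = config$rC, KA = config$KA, KC = config$KC)
    traj <- analytic_crm(pars, c(parsed$x1_0[s], parsed$x2_0[s], parsed$A[s, 1]),
                         per_sample$t_star[s], parsed$times)
    trajectories[[s]] <- traj
    nitrate_mse[s] <- mean((traj$nitrate - parsed$A[s, ])^2)
    b1_err[s] <- (traj$biomass1[length(parsed$times)] - parsed$x1_T[s])^2
    b2_err[s] <- (traj$biomass2[length(parsed$times)] - parsed$x2_T[s])^2
  }
  per_sample$nitrate_mse <- nitrate_mse
  per_sample$biomass1_sq_error <- b1_err
  per_sample$biomass2_sq_error <- b2_err

  structure(list(
    gamma1 = gamma1, gamma2 = gamma2,
    per_sample = per_sample,
    grid = tibble::as_tibble(grid) |> dplyr::mutate(total_objective = totals),
    trajectories = setNames(trajectories, parsed$sample_id),
    times = parsed$times,
    config = config,
    total_objective = best_fit$total
  ), class = "crm_fit")
}

#' @export
print.crm_fit <- function(x, ...) {
  cat(sprintf("<crm_fit> gamma1 = %.3g, gamma2 = %.3g (1/mM), %d samples, total objective %.4g\n",
              x$gamma1, x$gamma2, nrow(x$per_sample), x$total_objective))
  invisible(x)
}

#' Abundance-matched randomized grouping
#'
#' Builds a null grouping in which the chosen group(s) are replaced by random
#' feature sets drawn from outside the true group whose summed initial
#' abundance (averaged over samples) matches the true group's within
#' `tolerance`. Used to test whether the fitted groups are special, or
#' whether any equally-heavy random assembly would do.
#'
#' @param truth Grouping tibble (`feature_id`, `true_group` or `group`) with
#'   groups 1 and 2.
#' @param feature_initial Tibble of per-feature initial abundances (first
#'   column `sample_id`).
#' @param which One of `"both"`, `"group1"`, `"group2"`.
#' @param tolerance Relative abundance-matching tolerance (default 0.05).
#' @param max_attempts Rejection-sampling cap (default 10000).
#' @param seed Integer seed.
#' @return A grouping tibble like `truth` (column `group`), with the
#'   randomized group(s) replaced; replaced features not in any group get 0.
#' @export
randomize_group <- function(truth, feature_initial, which = c("both", "group1", "group2"),
                            tolerance = 0.05, max_attempts = 10000, seed = 1) {
  which <- match.arg(which)
  t_group <- if ("true_group" %in% names(truth)) truth$true_group else truth$group
  ids <- as.character(truth$feature_id)
  X0 <- as_sample_matrix(feature_initial, "feature_initial")
  mean_x0 <- colMeans(X0)[ids]
  to_replace <- switch(which, both = c(1L, 2L), group1 = 1L, group2 = 2L)

  with_seed(seed, function() {
    new_group <- t_group
    new_group[t_group %in% to_replace] <- 0L
    taken <- character(0)
    kept <- setdiff(c(1L, 2L), to_replace)
    for (g in to_replace) {
      members <- ids[t_group == g]
      target <- sum(mean_x0[members])
      # never draw from the replaced group itself, from groups that are kept
      # intact, or from features already used by another null group
      pool <- setdiff(ids, c(members, ids[t_group %in% kept], taken))
      if (length(pool) <= length(members)) {
        abort("feature pool too small for randomization",
              class = "funclust_bad_input")
      }
      found <- FALSE
      for (att in seq_len(max_attempts)) {
        # Greedy random assembly: add features until the target is reached.
        cand <- character(0); tot <- 0
        for (fid in sample(pool)) {
          if (tot >= target * (1 - tolerance)) break
          cand <- c(cand, fid); tot <- tot + mean_x0[fid]
        }
        if (abs(tot - target) / target <= tolerance) {
          new_group[match(cand, ids)] <- g
          taken <- c(taken, cand)
          found <- TRUE
          break
        }
      }
      if (!found) {
        abort(sprintf("could not match group %d abundance within %.0f%% in %d attempts",
                      g, 100 * tolerance, max_attempts),
              class = "funclust_randomization_failure")
      }
    }
    tibble::tibble(feature_id = ids, group = new_group)
  })
}

# Build a fit-ready observations tibble for an arbitrary grouping of a
# crm_dataset: group biomasses are summed from the per-feature tables; the
# observed nitrate series is unchanged.
observations_for_grouping <- function(dataset, grouping) {
  X0 <- as_sample_matrix(dataset$feature_initial, "feature_initial")
  XT <- as_sample_matrix(dataset$feature_final, "feature_final")
  labels <- if ("group" %in% names(grouping)) grouping$group else grouping$true_group
  g <- labels[match(colnames(X0), grouping$feature_id)]
  obs <- dataset$observations
  obs$x1_0 <- rowSums(X0[, g == 1, drop = FALSE])
  obs$x2_0 <- rowSums(X0[, g == 2, drop = FALSE])
  obs$x1_T <- rowSums(XT[, g == 1, drop = FALSE])
  obs$x2_T <- rowSums(XT[, g == 2, drop = FALSE])
  obs
}

#' Null-model comparison for a fitted grouping
#'
#' Refits the consumer-resource model on abundance-matched random groupings
#' and compares the resulting error distributions (biomass 1, biomass 2, and
#' nitrate mean squared errors, each summed over samples) to the errors of
#' the supplied grouping. One-sided empirical p-values use the add-one
#' convention \eqn{p = (1 + \#\{null \le true\}) / (1 + n_{null})}.
#'
#' @param dataset A `crm_dataset` (see [generate_crm_dataset()]), or any list
#'   with `observations`, `feature_initial`, `feature_final`.
#' @param grouping Grouping tibble to test (groups 1 and 2).
#' @param n_null Number of null groupings per mode (>= 20).
#' @param modes Randomization modes to run (subset of
#'   `c("both", "group1", "group2")`).
#' @param config A [crm_fit_config()]; null fitting is typically run with a
#'   coarser grid than the primary fit.
#' @param seed Integer seed.
#' @return An object of class `crm_null`: `true_errors` (named vector),
#'   `null_errors` (tibble: `mode`, `draw`, `biomass1`, `biomass2`,
#'   `nitrate`), `p_values` (tibble: `mode`, `error_type`, `p`).
#' @export
null_model_comparison <- function(dataset, grouping, n_null = 100,
                                  modes = c("both", "group1", "group2"),
                                  config = crm_fit_config(gamma_grid_points = 4,
                                                          n_restarts = 1,
                                                          maxit = 150,
                                                          refine_maxit = 25,
                                                          reltol = 1e-6),
                                  seed = 1) {
  stopifnot(n_null >= 20)
  modes <- match.arg(modes, several.ok = TRUE)

  fit_errors <- function(obs, fit_seed) {
    fit <- fit_crm(obs, config, seed = fit_seed)
    c(biomass1 = sum(fit$per_sample$biomass1_sq_error),
      biomass2 = sum(fit$per_sample$biomass2_sq_error),
      nitrate = sum(fit$per_sample$nitrate_mse))
  }

  true_errors <- fit_errors(observations_for_grouping(dataset, grouping), seed)

  seeds <- derive_seeds(seed, n_null * length(modes))
  rows <- list()
  k <- 0
  for (mode in modes) {
    for (d in seq_len(n_null)) {
      k <- k + 1
      null_grouping <- randomize_group(grouping, dataset$feature_initial,
                                       which = mode, seed = seeds[k])
      err <- fit_errors(observations_for_grouping(dataset, null_grouping),
                        seeds[k])
      rows[[k]] <- tibble::tibble(mode = mode, draw = d,
                                  biomass1 = err["biomass1"],
                                  biomass2 = err["biomass2"],
                                  nitrate = err["nitrate"])
    }
  }
  null_errors <- dplyr::bind_rows(rows)

  p_values <- null_errors |>
    tidyr::pivot_longer(cols = c("biomass1", "biomass2", "nitrate"),
                        names_to = "error_type", values_to = "error") |>
    dplyr::group_by(.data$mode, .data$error_type) |>
    dplyr::summarise(
      p = (1 + sum(.data$error <= true_errors[unique(.data$error_type)])) /
        (1 + dplyr::n()),
      .groups = "drop")

  structure(list(true_errors = true_errors, null_errors = null_errors,
                 p_values = p_values, n_null = n_null),
            class = "crm_null")
}

#' @export
print.crm_null <- function(x, ...) {
  cat(sprintf("<crm_null> %d nulls per mode\n", x$n_null))
  print(as.data.frame(x$p_values), row.names = FALSE)
  invisible(x)
}
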
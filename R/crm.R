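# Two-biomass consumer-resource model for nitrate reduction.
#
# State (x1, x2, A, C): two group biomasses growing on nitrate A (mM) and
# carbon C, with Monod saturation in both resources:
#   x1' = gamma1 r1 x1 * A/(A+KA) * C/(C+KC)
#   x2' = gamma2 r2 x2 * A/(A+KA) * C/(C+KC)
#   A'  = -(r1 x1 + r2 x2) * A/(A+KA)
#   C'  = -(x1 + rC x2) * C/(C+KC)
# gamma_i are yields (1/mM), r_i nitrate reduction rates (mM/day), rC the
# relative carbon consumption rate of biomass 2. With small affinities
# (KA = KC = 1e-3 mM) the dynamics are well approximated by exponential
# growth until carbon runs out at time t*, after which biomass is constant
# and A declines linearly.

#' Consumer-resource model parameters
#'
#' @param gamma1,gamma2 Yields of the two biomasses (1/mM).
#' @param r1,r2 Nitrate reduction rates (mM/day).
#' @param rC Relative carbon consumption rate of biomass 2 (dimensionless,
#'   default 1).
#' @param KA,KC Monod affinities for nitrate and carbon (mM, default 1e-3).
#' @return A list of class `crm_parameters`.
#' @export
crm_parameters <- function(gamma1, gamma2, r1, r2, rC = 1, KA = 1e-3, KC = 1e-3) {
  p <- list(gamma1 = gamma1, gamma2 = gamma2, r1 = r1, r2 = r2,
            rC = rC, KA = KA, KC = KC)
  if (any(unlist(p) < 0)) abort("CRM parameters must be non-negative",
                                class = "funclust_bad_input")
  structure(p, class = "crm_parameters")
}

#' Right-hand side of the consumer-resource ODE system
#'
#' @param state Numeric vector `c(x1, x2, A, C)` (non-negative).
#' @param params A [crm_parameters()].
#' @return Numeric vector of time derivatives `c(dx1, dx2, dA, dC)`.
#' @export
crm_rhs <- function(state, params) {
  if (any(state < 0)) abort("negative state", class = "funclust_bad_input")
  x1 <- state[1]; x2 <- state[2]; A <- state[3]; C <- state[4]
  mA <- A / (A + params$KA)
  mC <- C / (C + params$KC)
  c(
    params$gamma1 * params$r1 * x1 * mA * mC,
    params$gamma2 * params$r2 * x2 * mA * mC,
    -(params$r1 * x1 + params$r2 * x2) * mA,
    -(x1 + params$rC * x2) * mC
  )
}

#' Numerically integrate the consumer-resource system
#'
#' Adaptive-step integration (lsoda via deSolve) of [crm_rhs()]; states are
#' floored at zero inside the right-hand side so trajectories remain
#' physical.
#'
#' @param params A [crm_parameters()].
#' @param init Named or positional initial state `c(x1, x2, A, C)`.
#' @param times Increasing vector of observation times (days).
#' @param rtol,atol Integration tolerances.
#' @return A tibble of class `crm_trajectory` with columns `time`, `biomass1`,
#'   `biomass2`, `nitrate`, `carbon`.
#' @export
simulate_crm <- function(params, init, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(init) == 4, all(diff(times) > 0), all(init >= 0))
  rhs <- function(t, y, p) list(crm_rhs(pmax(y, 0), p))
  sol <- deSolve::ode(y = unname(init), times = times, func = rhs,
                      parms = params, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort(sprintf("CRM integration failed over [%g, %g]",
                  min(times), max(times)),
          class = "funclust_integration_failure")
  }
  out <- tibble::tibble(time = sol[, 1],
                        biomass1 = pmax(sol[, 2], 0),
                        biomass2 = pmax(sol[, 3], 0),
                        nitrate = pmax(sol[, 4], 0),
                        carbon = pmax(sol[, 5], 0))
  class(out) <- c("crm_trajectory", class(out))
  out
}

# Nitrate consumed by consumer i over [0, t] in the replete phase:
# r_i x_i(0) (exp(gamma_i r_i t) - 1) / (gamma_i r_i), with the r_i x_i(0) t
# limit when gamma_i r_i is (near) zero.
replete_consumption <- function(r, gamma, x0, t) {
  gr <- gamma * r
  if (gr > 1e-12) r * x0 * expm1(gr * t) / gr else r * x0 * t
}

#' Piecewise-analytic approximation of the consumer-resource dynamics
#'
#' While both resources are replete the Monod factors are ~1, so biomasses
#' grow exponentially, \eqn{x_i(t) = x_i(0) e^{\gamma_i r_i t}}, and nitrate
#' declines by the matching integral. At the carbon depletion time `t_star`
#' growth ceases: biomasses stay constant and nitrate declines linearly at
#' rate \eqn{r_1 x_1(t^*) + r_2 x_2(t^*)}, floored at zero. Fitting searches
#' over `t_star` instead of the (unobserved) initial carbon.
#'
#' @inheritParams simulate_crm
#' @param init Initial state `c(x1, x2, A)` (carbon is implicit in `t_star`).
#' @param t_star Carbon depletion time (days, >= 0). `t_star = 0` is the
#'   growth-inhibited regime: constant biomass, linear nitrate decline.
#' @return A `crm_trajectory` tibble (carbon is `NA`: it is internal to the
#'   approximation).
#' @export
analytic_crm <- function(params, init, t_star, times) {
  stopifnot(t_star >= 0, length(init) >= 3)
  x1_0 <- init[1]; x2_0 <- init[2]; A0 <- init[3]
  g1r1 <- params$gamma1 * params$r1
  g2r2 <- params$gamma2 * params$r2
  t_rep <- pmin(times, t_star)
  x1 <- x1_0 * exp(g1r1 * t_rep)
  x2 <- x2_0 * exp(g2r2 * t_rep)
  A <- A0 -
    replete_consumption(params$r1, params$gamma1, x1_0, t_rep) -
    replete_consumption(params$r2, params$gamma2, x2_0, t_rep)
  late <- times > t_star
  if (any(late)) {
    x1_star <- x1_0 * exp(g1r1 * t_star)
    x2_star <- x2_0 * exp(g2r2 * t_star)
    A_star <- A0 -
      replete_consumption(params$r1, params$gamma1, x1_0, t_star) -
      replete_consumption(params$r2, params$gamma2, x2_0, t_star)
    rate <- params$r1 * x1_star + params$r2 * x2_star
    A[late] <- A_star - rate * (times[late] - t_star)
  }
  out <- tibble::tibble(time = unname(times), biomass1 = unname(x1),
                        biomass2 = unname(x2), nitrate = unname(pmax(A, 0)),
                        carbon = NA_real_)
  class(out) <- c("crm_trajectory", class(out))
  out
}

#' Initial carbon that depletes at a given time
#'
#' Under the replete-phase approximation, carbon is consumed at rate
#' \eqn{x_1(t) + r_C x_2(t)}; integrating to `t_star` gives the initial
#' carbon stock for which depletion occurs exactly then. Useful for
#' constructing numeric reference trajectories that match the analytic
#' approximation.
#'
#' @inheritParams analytic_crm
#' @return Initial carbon (same units as biomass x time).
#' @export
crm_c0_for_tstar <- function(params, init, t_star) {
  replete_consumption(1, params$gamma1 * params$r1, init[1], t_star) +
    params$rC * replete_consumption(1, params$gamma2 * params$r2, init[2], t_star)
}

#' Generate a synthetic community dataset with consumer-resource dynamics
#'
#' Emulates a nitrate-amended incubation series: per-sample feature
#' abundances, two ground-truth functional groups that act as the model's two
#' biomasses, and a nitrate trajectory generated by the piecewise-analytic
#' dynamics. Features outside the two groups are inert background. Defaults
#' mirror a typical soil slurry protocol: 2 mM amended nitrate observed at 10
#' time points over 4 days.
#'
#' @param n_samples Number of samples (incubations).
#' @param n_features Total features; the first `group_size` form group 1, the
#'   next `group_size` group 2, the rest background.
#' @param group_size Features per functional group (default 4).
#' @param gamma1,gamma2 Global yields (defaults 0.4 and 2.44 1/mM).
#' @param r_range Range of per-sample rates r1, r2 (mM/day), drawn uniformly.
#' @param t_star_range Range of per-sample carbon depletion times (days).
#' @param A0 Initial nitrate (mM, default 2).
#' @param times Observation times (days).
#' @param noise_sd Multiplicative log-normal noise level on observed nitrate
#'   (0 = noiseless).
#' @param seed Integer seed.
#' @return A list of class `crm_dataset`: `observations` (tibble, one row per
#'   sample: endpoints and nitrate columns `A_<time>`), `feature_initial` /
#'   `feature_final` (tibbles of per-feature abundances), `truth` (grouping
#'   tibble with groups 1, 2 and 0 = background), `params_true` (tibble of
#'   per-sample r1, r2, t_star), `times`, `gamma1`, `gamma2`.
#' @export
generate_crm_dataset <- function(n_samples = 5, n_features = 20, group_size = 4,
                                 gamma1 = 0.4, gamma2 = 2.44,
                                 r_range = c(0.4, 1.0), t_star_range = c(0.8, 1.6),
                                 A0 = 2, times = seq(0, 4, length.out = 10),
                                 noise_sd = 0, seed = 1) {
  stopifnot(n_features >= 2 * group_size + 1, times[1] == 0)
  assignment <- c(rep(1L, group_size), rep(2L, group_size),
                  rep(0L, n_features - 2 * group_size))
  feature_ids <- paste0("asv", seq_len(n_features))
  sample_ids <- paste0("sample", seq_len(n_samples))
  T_end <- max(times)

  out <- with_seed(seed, function() {
    X0 <- matrix(runif(n_samples * n_features, 0.005, 0.025), nrow = n_samples)
    r1 <- runif(n_samples, r_range[1], r_range[2])
    r2 <- runif(n_samples, r_range[1], r_range[2])
    t_star <- runif(n_samples, t_star_range[1], t_star_range[2])
    XT <- X0
    A_obs <- matrix(0, n_samples, length(times))
    for (s in seq_len(n_samples)) {
      pars <- crm_parameters(gamma1, gamma2, r1[s], r2[s])
      x1_0 <- sum(X0[s, assignment == 1])
      x2_0 <- sum(X0[s, assignment == 2])
      traj <- analytic_crm(pars, c(x1_0, x2_0, A0), t_star[s], times)
      A_obs[s, ] <- traj$nitrate
      grow1 <- exp(gamma1 * r1[s] * min(t_star[s], T_end))
      grow2 <- exp(gamma2 * r2[s] * min(t_star[s], T_end))
      XT[s, assignment == 1] <- X0[s, assignment == 1] * grow1
      XT[s, assignment == 2] <- X0[s, assignment == 2] * grow2
    }
    if (noise_sd > 0) {
      A_obs <- A_obs * exp(matrix(rnorm(length(A_obs), sd = noise_sd),
                                  nrow = n_samples))
    }
    list(X0 = X0, XT = XT, A_obs = A_obs, r1 = r1, r2 = r2, t_star = t_star)
  })

  dimnames(out$X0) <- list(sample_ids, feature_ids)
  dimnames(out$XT) <- list(sample_ids, feature_ids)
  A_cols <- paste0("A_", format(times, trim = TRUE))
  obs <- tibble::tibble(
    sample_id = sample_ids,
    x1_0 = unname(rowSums(out$X0[, assignment == 1, drop = FALSE])),
    x2_0 = unname(rowSums(out$X0[, assignment == 2, drop = FALSE])),
    x1_T = unname(rowSums(out$XT[, assignment == 1, drop = FALSE])),
    x2_T = unname(rowSums(out$XT[, assignment == 2, drop = FALSE])))
  for (j in seq_along(times)) obs[[A_cols[j]]] <- out$A_obs[, j]

  structure(list(
    observations = obs,
    feature_initial = matrix_to_tibble(out$X0),
    feature_final = matrix_to_tibble(out$XT),
    truth = tibble::tibble(feature_id = feature_ids, true_group = assignment),
    params_true = tibble::tibble(sample_id = sample_ids, r1 = out$r1,
                                 r2 = out$r2, t_star = out$t_star),
    times = times, gamma1 = gamma1, gamma2 = gamma2, A0 = A0,
    seed = seed
  ), class = "crm_dataset")
}

#' @export
print.crm_dataset <- function(x, ...) {
  cat(sprintf(
    "<crm_dataset> %d samples, %d features (2 groups of %d), %d nitrate time points over %g days\n",
    nrow(x$observations), nrow(x$truth), sum(x$truth$true_group == 1),
    length(x$times), max(x$times)))
  invisible(x)
}
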
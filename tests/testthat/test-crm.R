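test_that("the ODE right-hand side matches direct substitution", {
  p <- crm_parameters(gamma1 = 1, gamma2 = 1, r1 = 1, r2 = 1)
  d <- crm_rhs(c(1, 1, 2, 1), p)
  mA <- 2 / (2 + 1e-3); mC <- 1 / (1 + 1e-3)
  expect_equal(d, c(mA * mC, mA * mC, -2 * mA, -2 * mC))

  # nitrate exhausted: growth and nitrate consumption stop
  d0 <- crm_rhs(c(1, 1, 0, 1), p)
  expect_equal(d0[1:3], c(0, 0, 0))
  expect_lt(d0[4], 0)
  # both resources exhausted: nothing moves
  expect_equal(crm_rhs(c(1, 1, 0, 0), p), rep(0, 4))

  # x2 = 0, r2 = 0 reduces to the single-biomass model
  p1 <- crm_parameters(gamma1 = 0.5, gamma2 = 1, r1 = 1, r2 = 0)
  d1 <- crm_rhs(c(1, 0, 2, 1), p1)
  expect_equal(d1[2], 0)
  expect_equal(d1[3], -1 * mA)

  expect_error(crm_rhs(c(-1, 0, 1, 1), p), class = "funclust_bad_input")
})

test_that("numeric integration respects conservation and convergence", {
  p <- crm_parameters(gamma1 = 0.5, gamma2 = 1.5, r1 = 1, r2 = 0.8,
                      KA = 1e-6, KC = 1e-6)
  times <- seq(0, 2, length.out = 21)

  # zero biomass: resources constant
  still <- simulate_crm(p, c(0, 0, 2, 5), times)
  expect_equal(still$nitrate, rep(2, 21), tolerance = 1e-7)
  expect_equal(still$carbon, rep(5, 21), tolerance = 1e-7)

  # yield bookkeeping with replete carbon and tiny affinities:
  # biomass gained = yield x nitrate consumed
  tr <- simulate_crm(p, c(0.05, 0.05, 2, 100), times)
  n <- nrow(tr)
  consumed <- tr$nitrate[1] - tr$nitrate[n]
  gained <- (tr$biomass1[n] - tr$biomass1[1]) / p$gamma1 +
    (tr$biomass2[n] - tr$biomass2[1]) / p$gamma2
  expect_gt(consumed, 0.1)
  expect_equal(gained, consumed, tolerance = 1e-4)

  # halving tolerances barely moves the endpoint
  hi <- simulate_crm(p, c(0.05, 0.05, 2, 1), times, rtol = 1e-8, atol = 1e-10)
  lo <- simulate_crm(p, c(0.05, 0.05, 2, 1), times, rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(hi$nitrate[n] - lo$nitrate[n]) / max(hi$nitrate[n], 1e-9), 1e-6)
})

test_that("the analytic approximation has the stated limits and exact yield identity", {
  p <- crm_parameters(gamma1 = 0.4, gamma2 = 2.44, r1 = 0.8, r2 = 0.6)
  times <- seq(0, 4, length.out = 10)

  # t* = 0: growth-inhibited regime, linear nitrate decline
  tr0 <- analytic_crm(p, c(0.1, 0.2, 2), t_star = 0, times)
  expect_equal(tr0$biomass1, rep(0.1, 10))
  expect_equal(tr0$biomass2, rep(0.2, 10))
  slope <- -(p$r1 * 0.1 + p$r2 * 0.2)
  expect_equal(tr0$nitrate, pmax(2 + slope * times, 0))

  # vanishing growth: consumer 1's nitrate term tends to r1 x1(0) t
  p_small <- crm_parameters(gamma1 = 1e-14, gamma2 = 1, r1 = 0.5, r2 = 0)
  tr_s <- analytic_crm(p_small, c(0.4, 0, 2), t_star = 4, times)
  expect_equal(tr_s$biomass1, rep(0.4, 10), tolerance = 1e-9)
  expect_equal(tr_s$nitrate, 2 - 0.5 * 0.4 * times, tolerance = 1e-9)

  # exact yield identity per consumer: x_i(t*) - x_i(0) = gamma_i * consumed_i
  t_star <- 1.5
  for (i in 1:2) {
    init <- c(0, 0, 2); init[i] <- 0.05
    tr <- analytic_crm(p, init, t_star, c(0, t_star))
    consumed <- tr$nitrate[1] - tr$nitrate[2]
    biomass <- if (i == 1) tr$biomass1 else tr$biomass2
    gamma <- if (i == 1) p$gamma1 else p$gamma2
    expect_equal(biomass[2] - biomass[1], gamma * consumed, tolerance = 1e-12)
  }
})

test_that("analytic and numeric solutions agree, and improve as affinities shrink", {
  times <- seq(0, 4, length.out = 41)
  init <- c(0.05, 0.04, 2)
  t_star <- 1.2
  rel_err <- sapply(c(1e-2, 1e-3, 1e-4), function(K) {
    p <- crm_parameters(gamma1 = 0.4, gamma2 = 2.44, r1 = 0.9, r2 = 0.7,
                        KA = K, KC = K)
    ana <- analytic_crm(p, init, t_star, times)
    C0 <- crm_c0_for_tstar(p, init, t_star)
    num <- simulate_crm(p, c(init, C0), times)
    max(abs(num$nitrate - ana$nitrate)) / max(ana$nitrate)
  })
  expect_lt(rel_err[2], 0.02)     # 2% at the default affinity 1e-3
  expect_true(all(diff(rel_err) < 0))  # monotone improvement as K -> 0

  # nitrate is non-increasing in both solvers
  p <- crm_parameters(gamma1 = 0.4, gamma2 = 2.44, r1 = 0.9, r2 = 0.7)
  ana <- analytic_crm(p, init, t_star, times)
  num <- simulate_crm(p, c(init, crm_c0_for_tstar(p, init, t_star)), times)
  expect_true(all(diff(ana$nitrate) <= 1e-12))
  expect_true(all(diff(num$nitrate) <= 1e-8))
  expect_true(all(diff(ana$biomass1) >= -1e-12))
  expect_true(all(diff(num$biomass1) >= -1e-8))
})

test_that("randomized groupings match the target abundance and stay disjoint", {
  ds <- generate_crm_dataset(n_samples = 3, n_features = 30, seed = 2)
  X0 <- colMeans(as.matrix(ds$feature_initial[, -1]))
  target1 <- sum(X0[ds$truth$true_group == 1])
  target2 <- sum(X0[ds$truth$true_group == 2])

  sums1 <- sums2 <- numeric(50)
  for (d in 1:50) {
    null <- randomize_group(ds$truth, ds$feature_initial, which = "both",
                            seed = d)
    # replaced groups draw only from outside the true groups' features
    expect_false(any(ds$truth$feature_id[ds$truth$true_group == 1] %in%
                       null$feature_id[null$group == 1]))
    expect_length(intersect(null$feature_id[null$group == 1],
                            null$feature_id[null$group == 2]), 0)
    sums1[d] <- sum(X0[null$group == 1])
    sums2[d] <- sum(X0[null$group == 2])
    expect_lte(abs(sums1[d] - target1) / target1, 0.05)
    expect_lte(abs(sums2[d] - target2) / target2, 0.05)
  }
  # the distribution of null sums centres on the target
  expect_equal(mean(sums1), target1, tolerance = 0.05)
  expect_equal(mean(sums2), target2, tolerance = 0.05)

  # determinism
  n1 <- randomize_group(ds$truth, ds$feature_initial, which = "group1", seed = 7)
  n2 <- randomize_group(ds$truth, ds$feature_initial, which = "group1", seed = 7)
  expect_identical(n1, n2)
  # single-group mode leaves the other group untouched
  expect_equal(n1$feature_id[n1$group == 2],
               ds$truth$feature_id[ds$truth$true_group == 2])
})

test_that("the synthetic CRM dataset is self-consistent", {
  ds <- generate_crm_dataset(n_samples = 4, seed = 5)
  obs <- ds$observations
  X0 <- as.matrix(ds$feature_initial[, -1])
  XT <- as.matrix(ds$feature_final[, -1])
  g <- ds$truth$true_group
  expect_equal(obs$x1_0, unname(rowSums(X0[, g == 1])))
  expect_equal(obs$x2_T, unname(rowSums(XT[, g == 2])))
  # background features never move
  expect_equal(X0[, g == 0], XT[, g == 0])
  # observed nitrate equals the analytic trajectory of the true parameters
  for (s in 1:4) {
    p <- crm_parameters(ds$gamma1, ds$gamma2, ds$params_true$r1[s],
                        ds$params_true$r2[s])
    tr <- analytic_crm(p, c(obs$x1_0[s], obs$x2_0[s], ds$A0),
                       ds$params_true$t_star[s], ds$times)
    expect_equal(unname(as.numeric(obs[s, grep("^A_", names(obs))])),
                 tr$nitrate)
  }
})
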
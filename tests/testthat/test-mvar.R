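test_that("two-node system construction follows the (a, c) parameterisation", {
  sys <- make_two_node_system(a = 0, c = 0)
  expect_equal(sys$A[1, 2], 0)
  expect_equal(sys$A[2, 1], 0)
  expect_equal(unname(sys$noise_cov), diag(2))

  sys <- make_two_node_system(a = 0.3, c = 0.4, s = 0.25)
  expect_equal(sys$A[1, 2], 0.3)
  expect_equal(unname(diag(sys$A)), c(0.25, 0.25))
  expect_equal(sys$noise_cov[1, 2], 0.4)

  expect_error(make_two_node_system(a = 0.2, c = 1), "noise correlation")
  expect_error(make_two_node_system(a = 0.9, c = 0, s = 0.5), "stationarity")
})

test_that("analytic stationary covariance solves the Lyapunov identity", {
  set.seed(101)
  for (k in 1:20) {
    sys <- random_stable_system()
    m <- analytic_stationary_cov(sys)
    lhs <- m$sigma0
    rhs <- sys$A %*% m$sigma0 %*% t(sys$A) + sys$noise_cov
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("analytic covariance matches closed forms and the white-noise case", {
  # scalar AR(1): stationary variance sigma^2 / (1 - a^2)
  sys <- phidnet:::new_mvar_system(matrix(0.5, 1, 1), matrix(1, 1, 1))
  m <- analytic_stationary_cov(sys)
  expect_equal(as.numeric(m$sigma0), 1 / (1 - 0.25), tolerance = 1e-12)
  expect_equal(as.numeric(m$sigma_tau), 0.5 / (1 - 0.25), tolerance = 1e-12)

  # A = 0: sigma0 = noise covariance, lagged covariance zero
  Se <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  sys <- phidnet:::new_mvar_system(matrix(0, 2, 2), Se)
  m <- analytic_stationary_cov(sys)
  expect_equal(unname(m$sigma0), Se)
  expect_equal(max(abs(m$sigma_tau)), 0)

  # lag convention: entry (i, j) = Cov(x_i(t - tau), x_j(t)) = [S0 A']_{ij}
  set.seed(7)
  sys <- random_stable_system(3)
  m2 <- analytic_stationary_cov(sys, tau = 2)
  expect_equal(unname(m2$sigma_tau),
               unname(m2$sigma0 %*% t(sys$A %*% sys$A)), tolerance = 1e-12)
})

test_that("analytic covariance agrees with the fixed-point oracle", {
  set.seed(11)
  for (k in 1:10) {
    sys <- random_stable_system()
    m <- analytic_stationary_cov(sys)
    expect_lt(max(abs(m$sigma0 - oracle_stationary_cov(sys$A, sys$noise_cov))),
              1e-9)
  }
})

test_that("simulate_mvar is reproducible and converges to the analytic model", {
  sys <- make_two_node_system(0.3, 0.2)
  x1 <- simulate_mvar(sys, 500, seed = 42)
  x2 <- simulate_mvar(sys, 500, seed = 42)
  expect_identical(x1, x2)
  expect_false(identical(x1, simulate_mvar(sys, 500, seed = 43)))
  expect_equal(dim(x1), c(500, 2))

  # white noise: sample covariance near identity
  wn <- phidnet:::new_mvar_system(matrix(0, 3, 3), diag(3))
  x <- simulate_mvar(wn, 50000, seed = 1)
  expect_lt(max(abs(stats::cov(x) - diag(3))), 0.05)

  # stable system: sample sigma0 and sigma_tau near analytic values
  m <- analytic_stationary_cov(sys)
  x <- simulate_mvar(sys, 100000, seed = 2)
  est <- estimate_lagged_model(x)
  expect_lt(max(abs(est$sigma0 - m$sigma0)), 0.05)
  expect_lt(max(abs(est$sigma_tau - m$sigma_tau)), 0.05)

  expect_error(simulate_mvar(sys, 0), "positive")
})

test_that("modular systems have the requested block structure", {
  ms <- make_modular_system(6, c(3, 3), within_coupling = 0.3,
                            between_coupling = 0, noise_corr_within = 0,
                            seed = 1)
  A <- ms$system$A
  expect_true(all(A[1:3, 4:6] == 0))
  expect_true(all(A[4:6, 1:3] == 0))
  expect_true(all(A[1:3, 1:3][upper.tri(diag(3))] > 0))
  expect_equal(unname(ms$system$noise_cov), diag(6))
  expect_equal(ms$partition$module, rep(c("M1", "M2"), each = 3))

  # determinism
  ms2 <- make_modular_system(6, c(3, 3), within_coupling = 0.3,
                             between_coupling = 0, noise_corr_within = 0,
                             seed = 1)
  expect_identical(ms$system$A, ms2$system$A)

  expect_error(make_modular_system(6, c(3, 4)), "sum to n_nodes")
})

test_that("disconnected modules carry no cross-module redundancy or phi_r", {
  ms <- make_modular_system(6, c(3, 3), within_coupling = 0.3,
                            between_coupling = 0, noise_corr_within = 0.3,
                            seed = 2)
  nets <- pairwise_networks(analytic_stationary_cov(ms$system))
  between <- outer(ms$partition$module, ms$partition$module, `!=`)
  expect_lt(max(abs(nets$redundancy$values[between])), 1e-10)
  expect_lt(max(abs(nets$phi_wms$values[between])), 1e-10)
  expect_lt(max(abs(nets$phi_r$values[between])), 1e-10)
  # MMI synergy between independent nodes sits at the self-predictability
  # floor: the smaller of the two single-node past->future MIs
  m <- analytic_stationary_cov(ms$system)
  expect_gt(min(nets$synergy$values[between]), 0)
  for (i in 1:3) for (j in 4:6) {
    J <- phidnet:::pair_joint_cov(m, i, j)
    floor_syn <- min(gaussian_mi(J, 1, 3), gaussian_mi(J, 2, 4))
    expect_equal(nets$synergy$values[i, j], floor_syn, tolerance = 1e-10)
  }
})

test_that("between-module coupling creates cross-module synergy surplus", {
  ms <- make_modular_system(6, c(3, 3), within_coupling = 0,
                            between_coupling = 0.3, noise_corr_within = 0,
                            seed = 3, between_density = 1)
  nets <- pairwise_networks(analytic_stationary_cov(ms$system),
                            measures = "synergy")
  between <- outer(ms$partition$module, ms$partition$module, `!=`)
  diag(between) <- FALSE
  within <- !between & !diag(6)
  expect_gt(mean(nets$synergy$values[between]),
            mean(nets$synergy$values[within]))
})

test_that("every emitted system is stationary", {
  set.seed(12)
  for (k in 1:50) {
    ms <- make_modular_system(8, c(4, 4), within_coupling = runif(1, 0, 0.5),
                              between_coupling = runif(1, 0, 0.3),
                              noise_corr_within = runif(1, 0, 0.5),
                              seed = k)
    expect_lt(phidnet:::spectral_radius(ms$system$A), 1)
  }
  pl <- make_planted_roles_system()
  expect_lt(phidnet:::spectral_radius(pl$system$A), 1)
})

test_that("group datasets respect design, effects, and reproducibility", {
  base <- make_modular_system(6, c(3, 3), seed = 1)$system
  ds <- simulate_group_dataset(base, 4, conditions = c("wake", "anesth"),
                               effect_edges = cbind(1, 2), effect_scale = 0.5,
                               n_timepoints = 50, design = "paired", seed = 9)
  expect_s3_class(ds, "group_dataset")
  expect_equal(nrow(ds), 8)
  # paired design: identical subject sets in both conditions
  expect_setequal(ds$subject_id[ds$condition == "wake"],
                  ds$subject_id[ds$condition == "anesth"])
  # all timeseries share region count and ordering
  expect_true(all(vapply(ds$ts, ncol, 1L) == 6))
  expect_true(all(vapply(ds$ts, function(x)
    identical(colnames(x), base$region_ids), TRUE)))

  ds2 <- simulate_group_dataset(base, 4, conditions = c("wake", "anesth"),
                                effect_edges = cbind(1, 2), effect_scale = 0.5,
                                n_timepoints = 50, design = "paired", seed = 9)
  expect_identical(ds$ts, ds2$ts)

  un <- simulate_group_dataset(base, 3, conditions = c("a", "b"),
                               n_timepoints = 50, design = "unpaired",
                               seed = 1)
  expect_equal(length(intersect(un$subject_id[un$condition == "a"],
                                un$subject_id[un$condition == "b"])), 0)

  expect_error(simulate_group_dataset(base, 0, n_timepoints = 50), "n_subjects")
  expect_error(simulate_group_dataset(base, 2, conditions = character(0),
                                      n_timepoints = 50), "empty")
  expect_error(simulate_group_dataset(base, 2, effect_edges = cbind(1, 99),
                                      n_timepoints = 50), "node range")
})

test_that("a suppressed coupling lowers phi_r on that edge at large T", {
  base <- make_two_node_system(a = 0.4, c = 0.1)
  m_base <- analytic_stationary_cov(base)
  ds <- simulate_group_dataset(base, 1, conditions = c("on", "off"),
                               effect_edges = cbind(1, 2), effect_scale = 0,
                               subject_jitter = 0, n_timepoints = 50000,
                               design = "paired", seed = 5)
  phi_on <- phiid_atoms_pair(estimate_lagged_model(
    ds$ts[[which(ds$condition == "on")]]), 1, 2)$phi_r
  phi_off <- phiid_atoms_pair(estimate_lagged_model(
    ds$ts[[which(ds$condition == "off")]]), 1, 2)$phi_r
  expect_gt(phi_on, phi_off)
})
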
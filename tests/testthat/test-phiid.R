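test_that("independent white-noise nodes carry no information atoms", {
  sys <- phidnet:::new_mvar_system(matrix(0, 2, 2), diag(2))
  at <- phiid_atoms_pair(analytic_stationary_cov(sys), 1, 2)
  for (m in c("tdmi", "redundancy", "synergy", "phi_wms", "phi_r")) {
    expect_lt(abs(at[[m]]), 1e-10)
  }
})

test_that("independent AR(1) nodes: zero redundancy and phi, floor synergy", {
  at <- phiid_atoms_pair(analytic_stationary_cov(two_node(a = 0, c = 0)), 1, 2)
  expect_lt(abs(at$redundancy), 1e-10)
  expect_lt(abs(at$phi_wms), 1e-10)
  expect_lt(abs(at$phi_r), 1e-10)
  # Under the MMI decomposition two independent self-predicting nodes keep
  # a synergy floor equal to the weaker node's self-MI
  expect_equal(at$synergy, -0.5 * log(1 - 0.2^2), tolerance = 1e-10)
})

test_that("coupling creates synergy; common noise creates redundancy", {
  at <- phiid_atoms_pair(analytic_stationary_cov(two_node(a = 0.4, c = 0)), 1, 2)
  floor_syn <- -0.5 * log(1 - 0.2^2)
  expect_gt(at$synergy, floor_syn)
  at2 <- phiid_atoms_pair(analytic_stationary_cov(two_node(a = 0, c = 0.8)), 1, 2)
  expect_gt(at2$redundancy, 0)
})

test_that("redundancy-dominated systems have negative phi but phi_r >= 0", {
  at <- phiid_atoms_pair(analytic_stationary_cov(two_node(a = 0.1, c = 0.9)),
                         1, 2)
  expect_lt(at$phi_wms, 0)
  expect_gte(at$phi_r, -1e-10)
  expect_equal(at$phi_r, at$phi_wms + at$redundancy, tolerance = 1e-12)
})

test_that("symmetric systems attain the redundancy minimum at a tie", {
  m <- analytic_stationary_cov(two_node(a = 0.3, c = 0.4))
  J <- phidnet:::pair_joint_cov(m, 1, 2)
  mi_xy <- gaussian_mi(J, 1, 4) # x_i past ; x_j future
  mi_yx <- gaussian_mi(J, 2, 3) # x_j past ; x_i future
  expect_equal(mi_xy, mi_yx, tolerance = 1e-10)
})

test_that("atoms satisfy their defining identities on random systems", {
  set.seed(31)
  for (k in 1:200) {
    sys <- random_stable_system()
    n <- length(sys$region_ids)
    ij <- sample(n, 2)
    at <- phiid_atoms_pair(analytic_stationary_cov(sys), ij[1], ij[2])
    expect_gte(at$tdmi, -1e-10)
    expect_gte(at$redundancy, -1e-10)
    expect_gte(at$synergy, -1e-10)
    expect_gte(at$phi_r, -1e-10)
    expect_equal(at$phi_r - at$phi_wms - at$redundancy, 0, tolerance = 1e-10)
    # MI monotone under source aggregation: single past <= joint past
    m <- analytic_stationary_cov(sys)
    J <- phidnet:::pair_joint_cov(m, ij[1], ij[2])
    expect_lte(gaussian_mi(J, 1, 3:4), at$tdmi + 1e-10)
    expect_lte(gaussian_mi(J, 2, 3:4), at$tdmi + 1e-10)
  }
})

test_that("pair atoms match the brute-force oracle", {
  set.seed(32)
  for (k in 1:30) {
    sys <- random_stable_system()
    at <- phiid_atoms_pair(analytic_stationary_cov(sys), 1, 2)
    or <- oracle_atoms(sys$A, sys$noise_cov)
    for (m in c("tdmi", "redundancy", "synergy", "phi_wms", "phi_r")) {
      expect_equal(at[[m]], or[[m]], tolerance = 1e-8)
    }
  }
})

test_that("estimated lagged models recover the VAR structure", {
  set.seed(33)
  sys <- random_stable_system(3)
  x <- simulate_mvar(sys, 100000, seed = 3)
  est <- estimate_lagged_model(x)
  expect_equal(est$n_samples_used, 100000 - 1)
  # sigma_tau ~= sigma0 A' under the (i,j) = Cov(x_i(t-1), x_j(t)) convention
  expect_lt(max(abs(est$sigma_tau - est$sigma0 %*% t(sys$A))), 0.05)

  expect_error(estimate_lagged_model(x[1:3, ], tau = 1), "tau")
  xc <- x
  xc[, 2] <- 1
  expect_error(estimate_lagged_model(xc), "zero-variance")
})

test_that("pairwise networks are symmetric, zero-diagonal and self-consistent", {
  set.seed(34)
  ms <- make_modular_system(6, c(3, 3), within_coupling = 0.25,
                            between_coupling = 0.1, noise_corr_within = 0.3,
                            seed = 4)
  model <- analytic_stationary_cov(ms$system)
  nets <- pairwise_networks(model)
  expect_named(nets, c("tdmi", "redundancy", "synergy", "phi_wms", "phi_r"))
  for (nw in nets) {
    expect_equal(nw$values, t(nw$values))
    expect_equal(unname(diag(nw$values)), rep(0, 6))
  }
  # entries equal individually computed pair atoms (vectorised == scalar path)
  for (i in 1:5) for (j in (i + 1):6) {
    at <- phiid_atoms_pair(model, i, j)
    for (m in names(nets)) {
      expect_equal(nets[[m]]$values[i, j], at[[m]], tolerance = 1e-9)
    }
  }
})

test_that("group averaging is element-wise and validates inputs", {
  set.seed(35)
  sys <- random_stable_system(3)
  nw <- pairwise_networks(analytic_stationary_cov(sys), measures = "phi_r")$phi_r
  expect_equal(group_average(list(nw))$values, nw$values)

  nw2 <- nw
  nw2$values <- nw$values * 3
  avg <- group_average(list(nw, nw2))
  expect_equal(avg$values, nw$values * 2)

  expect_error(group_average(list()), "empty")
  other <- pairwise_networks(analytic_stationary_cov(sys),
                             measures = "synergy")$synergy
  expect_error(group_average(list(nw, other)), "share")
})

test_that("subject-ensemble averages converge to the analytic network", {
  sys <- make_modular_system(4, c(2, 2), within_coupling = 0.3,
                             noise_corr_within = 0.2, seed = 6)$system
  truth <- pairwise_networks(analytic_stationary_cov(sys),
                             measures = "phi_r")$phi_r
  ds <- simulate_group_dataset(sys, 8, conditions = "rest",
                               subject_jitter = 0, n_timepoints = 20000,
                               seed = 8)
  avg <- group_average(lapply(ds$ts, function(x)
    pairwise_networks(x, measures = "phi_r")$phi_r))
  expect_lt(max(abs(avg$values - truth$values)), 0.01)
})

test_that("per-atom estimates converge to analytic values as T grows", {
  sys <- make_modular_system(6, c(3, 3), within_coupling = 0.25,
                             between_coupling = 0.1, noise_corr_within = 0.3,
                             seed = 5)$system
  truth <- pairwise_networks(analytic_stationary_cov(sys))
  err <- sapply(c(1e3, 1e4, 1e5), function(T_) {
    nets <- pairwise_networks(simulate_mvar(sys, T_, seed = 77))
    stats::median(abs(unlist(lapply(names(nets), function(m)
      nets[[m]]$values[upper.tri(diag(6))] -
        truth[[m]]$values[upper.tri(diag(6))]))))
  })
  expect_true(all(diff(err) < 0))
})
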
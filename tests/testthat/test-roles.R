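pc_net <- function(V) {
  phidnet:::new_info_network(V, "synergy", paste0("R", seq_len(nrow(V))), 1L)
}

test_that("participation coefficient matches hand-computed cases", {
  # all connections inside the own module -> P = 0
  V <- matrix(0, 6, 6)
  V[1, 2] <- V[2, 1] <- 1
  V[1, 3] <- V[3, 1] <- 2
  part <- tibble::tibble(region = paste0("R", 1:6),
                         module = rep(c("a", "b"), each = 3))
  expect_equal(participation_coefficient(pc_net(V), part)$pc[1], 0)

  # equal strength to all M = 8 modules -> 1 - 8 (1/8)^2 = 0.875
  V8 <- matrix(0, 9, 9)
  V8[1, 2:9] <- V8[2:9, 1] <- 1
  part8 <- tibble::tibble(region = paste0("R", 1:9),
                          module = c("m1", paste0("m", 1:8)))
  expect_equal(participation_coefficient(pc_net(V8), part8)$pc[1],
               1 - 8 * (1 / 8)^2)

  # half in-module, half to one other module -> 1 - (0.25 + 0.25) = 0.5
  Vh <- matrix(0, 4, 4)
  Vh[1, 2] <- Vh[2, 1] <- 1
  Vh[1, 3] <- Vh[3, 1] <- 1
  parth <- tibble::tibble(region = paste0("R", 1:4),
                          module = c("a", "a", "b", "b"))
  expect_equal(participation_coefficient(pc_net(Vh), parth)$pc[1], 0.5)
})

test_that("participation coefficient respects its analytic bounds", {
  set.seed(51)
  for (k in 1:200) {
    n <- sample(6:12, 1)
    M <- sample(2:4, 1)
    V <- matrix(runif(n * n), n, n)
    V <- V + t(V)
    diag(V) <- 0
    part <- tibble::tibble(region = paste0("R", 1:n),
                           module = paste0("m", sample(M, n, replace = TRUE)))
    while (length(unique(part$module)) < 2) {
      part$module <- paste0("m", sample(M, n, replace = TRUE))
    }
    pc <- participation_coefficient(pc_net(V), part)$pc
    expect_true(all(pc >= 0))
    expect_true(all(pc <= 1 - 1 / length(unique(part$module)) + 1e-12))
    # global rescaling invariance
    pc2 <- participation_coefficient(pc_net(V * 13), part)$pc
    expect_equal(pc, pc2, tolerance = 1e-12)
  }
})

test_that("zero-strength and negative entries are handled per the definition", {
  V <- matrix(0, 4, 4)
  V[1, 2] <- V[2, 1] <- 1
  V[3, 4] <- V[4, 3] <- -1 # negative entries excluded
  part <- tibble::tibble(region = paste0("R", 1:4),
                         module = c("a", "b", "a", "b"))
  expect_message(pc <- participation_coefficient(pc_net(V), part),
                 "zero positive strength")
  expect_equal(pc$pc[3], 0)
  expect_equal(pc$pc[4], 0)
  expect_error(participation_coefficient(pc_net(V), part[1:2, ]),
               "does not label")
})

test_that("workspace roles partition into gateway/broadcaster/unclassified", {
  prof <- tibble::tibble(
    region = paste0("R", 1:4),
    workspace = c(TRUE, TRUE, FALSE, TRUE),
    pc_syn = c(0.9, 0.1, 0.5, 0.5),
    pc_red = c(0.1, 0.9, 0.5, 0.5))
  out <- classify_workspace_roles(prof)
  expect_equal(out$role, c("gateway", "broadcaster", "non-workspace",
                           "unclassified"))
  expect_true(all(out$role[out$workspace] %in%
                    c("gateway", "broadcaster", "unclassified")))
  expect_true(all(out$role[!out$workspace] == "non-workspace"))

  single <- tibble::tibble(region = "R1", workspace = TRUE,
                           pc_syn = 0.3, pc_red = 0.6)
  expect_equal(classify_workspace_roles(single)$role, "unclassified")

  empty <- tibble::tibble(region = "R1", workspace = FALSE,
                          pc_syn = 0.3, pc_red = 0.6)
  expect_warning(out <- classify_workspace_roles(empty), "empty workspace")
  expect_equal(out$role, "non-workspace")
})

test_that("partition agreement is a plain correlation with guards", {
  p <- tibble::tibble(region = paste0("R", 1:5), pc = c(0.1, 0.3, 0.5, 0.7, 0.2))
  expect_equal(partition_agreement(p, p), 1)
  q <- p
  q$pc <- 1 - p$pc
  expect_equal(partition_agreement(p, q), -1)
  set.seed(52)
  a <- runif(10)
  b <- runif(10)
  expect_equal(partition_agreement(a, b),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
  expect_error(partition_agreement(rep(0.5, 4), runif(4)), "constant")
})

test_that("planted gateway and broadcaster are recovered from group data", {
  pl <- make_planted_roles_system()
  hits <- sapply(1:20, function(sd_) {
    ds <- simulate_group_dataset(pl$system, 10, conditions = "rest",
                                 subject_jitter = 0.02, n_timepoints = 5000,
                                 seed = sd_)
    nets <- lapply(ds$ts, pairwise_networks,
                   measures = c("synergy", "redundancy"))
    prof <- node_profiles(
      group_average(lapply(nets, `[[`, "synergy")),
      group_average(lapply(nets, `[[`, "redundancy")),
      pl$partition)
    prof$role[prof$region == pl$gateway] == "gateway" &&
      prof$role[prof$region == pl$broadcaster] == "broadcaster"
  })
  expect_gte(mean(hits), 0.9)
})
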
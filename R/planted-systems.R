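# Planted benchmark systems with analytically known ground-truth roles.
#
# Constructing a node whose synergistic interactions span modules while its
# redundant interactions stay local (a gateway), or the converse (a
# broadcaster), requires care: in VAR(1) dynamics any strong reciprocal
# coupling generates lagged correlation, hence redundancy, in the same
# places it generates synergy. Three quasi-orthogonal mechanisms are used
# here:
#   * directed (one-way) driving creates synergistic interactions with
#     little redundancy, because the minimum over both lagged directions in
#     the redundancy definition is dominated by the weak reverse path;
#   * a common driver with self-memory makes its targets mutually
#     redundant (the driver's past is duplicated into every target);
#   * weak reciprocal edges create a balanced mix, usable as a localised
#     redundancy anchor.
# Ground-truth labels refer to the population (analytic-covariance)
# profiles, which the estimation pipeline should recover from finite data.

#' Planted gateway/broadcaster system
#'
#' A 12-region, 3-module system with two designated workspace hubs whose
#' roles are known by construction. Region `R1` (the gateway) drives one
#' region in each module one-way -- module-spanning synergy -- and shares
#' weak reciprocal edges only inside its own module, so its redundancy is
#' local. Region `R5` (the broadcaster) drives its own module one-way --
#' local synergy -- while listening to the module drivers of the two other
#' modules, which duplicates their signals into it and spreads its
#' redundancy across modules. Each module also contains a memory-carrying
#' driver (making its peripheral regions strongly and locally redundant,
#' which keeps them out of the workspace) and weakly coupled peripherals.
#'
#' At the population level the node-profile pipeline classifies `R1` as a
#' gateway and `R5` as a broadcaster; with group-averaged estimates from
#' simulated data the labels are recovered with high probability.
#'
#' @return A list: `system` (an `mvar_system`), `partition` (tibble),
#'   `gateway` and `broadcaster` (region ids of the planted hubs).
#' @export
#' @examples
#' pl <- make_planted_roles_system()
#' nets <- pairwise_networks(analytic_stationary_cov(pl$system),
#'                           measures = c("synergy", "redundancy"))
#' node_profiles(nets$synergy, nets$redundancy, pl$partition)
make_planted_roles_system <- function() {
  n <- 12
  module <- rep(1:3, each = 4) # M1 = {1..4}, M2 = {5..8}, M3 = {9..12}
  A <- matrix(0, n, n)
  bidir <- function(i, j, v) {
    A[i, j] <<- v
    A[j, i] <<- v
  }
  # weak peripheral coupling inside modules
  bidir(3, 4, 0.1)
  bidir(7, 8, 0.1)
  bidir(9, 11, 0.1)
  bidir(9, 12, 0.1)
  bidir(11, 12, 0.1)
  # module drivers (2, 6, 10) duplicate their signal into peripherals
  for (t in c(3, 4)) A[t, 2] <- 0.5
  for (t in c(7, 8)) A[t, 6] <- 0.5
  for (t in c(9, 11, 12)) A[t, 10] <- 0.5
  A[6, 2] <- 0.3; A[10, 6] <- 0.3; A[2, 10] <- 0.3 # driver ring
  # gateway R1: one-way driving into every module; local redundancy anchor
  for (t in c(7, 9, 3)) A[t, 1] <- 0.5
  bidir(1, 3, 0.25)
  bidir(1, 4, 0.25)
  # broadcaster R5: one-way driving of its own module; listens to the
  # drivers of the two other modules (module-spanning redundancy)
  for (t in c(6, 7, 8)) A[t, 5] <- 0.55
  A[5, 2] <- 0.3
  A[5, 10] <- 0.3
  diag(A) <- 0.15
  for (d in c(2, 6, 10)) A[d, d] <- 0.25
  rho <- spectral_radius(A)
  if (rho >= 0.95) A <- A * (0.9 / rho)
  region_ids <- paste0("R", seq_len(n))
  list(
    system = new_mvar_system(A, diag(n), region_ids),
    partition = tibble::tibble(region = region_ids,
                               module = paste0("M", module)),
    gateway = "R1",
    broadcaster = "R5"
  )
}

#' Planted synergy-hub / redundancy-hub system
#'
#' The same architecture as [make_planted_roles_system()], labelled for
#' workspace recovery. The designated synergy hubs are the two coupling
#' hubs `R1` and `R5`, whose information dynamics are dominated by one-way
#' driving (high synergistic strength, modest redundancy); the designated
#' redundancy hubs are the driver-fed peripherals `R11` and `R12`, whose
#' signals are largely duplicated copies of their module driver (high
#' redundant strength, little synergy beyond the floor). The
#' synergy-minus-redundancy rank gradient should place the synergy hubs
#' inside the workspace and the redundancy hubs outside it.
#'
#' @return A list: `system`, `partition`, `synergy_hubs`,
#'   `redundancy_hubs` (region id vectors).
#' @export
make_planted_workspace_system <- function() {
  pl <- make_planted_roles_system()
  list(
    system = pl$system,
    partition = pl$partition,
    synergy_hubs = c("R1", "R5"),
    redundancy_hubs = c("R11", "R12")
  )
}
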
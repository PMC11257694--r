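# Independent brute-force oracle for Gaussian information quantities.
# Deliberately separate numerical routes from the package:
#  - log-determinants via symmetric eigendecomposition (package uses Cholesky);
#  - stationary covariance via fixed-point iteration of the Lyapunov map
#    (package solves the vectorised linear system);
#  - every MI term evaluated from first principles, atoms assembled from
#    the definitions.

oracle_logdet <- function(S) {
  sum(log(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values))
}

oracle_mi <- function(J, u, v) {
  0.5 * (oracle_logdet(J[u, u, drop = FALSE]) +
           oracle_logdet(J[v, v, drop = FALSE]) -
           oracle_logdet(J[c(u, v), c(u, v), drop = FALSE]))
}

oracle_stationary_cov <- function(A, Se, tol = 1e-14, max_iter = 100000) {
  S <- Se
  for (i in seq_len(max_iter)) {
    S_new <- A %*% S %*% t(A) + Se
    if (max(abs(S_new - S)) < tol) return(S_new)
    S <- S_new
  }
  stop("oracle Lyapunov iteration did not converge")
}

# Joint covariance of (x_i(t-tau), x_j(t-tau), x_i(t), x_j(t))
oracle_pair_cov <- function(A, Se, i, j, tau = 1) {
  S0 <- oracle_stationary_cov(A, Se)
  Ak <- diag(nrow(A))
  for (k in seq_len(tau)) Ak <- Ak %*% A
  L <- S0 %*% t(Ak)
  idx <- c(i, j)
  rbind(cbind(S0[idx, idx], L[idx, idx]),
        cbind(t(L[idx, idx]), S0[idx, idx]))
}

oracle_atoms <- function(A, Se, i = 1, j = 2, tau = 1) {
  J <- oracle_pair_cov(A, Se, i, j, tau)
  p <- 1:2
  f <- 3:4
  tdmi <- oracle_mi(J, p, f)
  mi_ss <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) mi_ss[a, b] <- oracle_mi(J, a, 2 + b)
  mi_sf <- c(oracle_mi(J, 1, f), oracle_mi(J, 2, f))
  red <- min(mi_ss)
  list(tdmi = tdmi,
       redundancy = red,
       synergy = tdmi - max(mi_sf),
       phi_wms = tdmi - mi_ss[1, 1] - mi_ss[2, 2],
       phi_r = tdmi - mi_ss[1, 1] - mi_ss[2, 2] + red,
       mi_sf = mi_sf)
}

# Random stable VAR(1) systems with random SPD innovation covariance.
random_stable_system <- function(n = NULL, coupling_sd = 0.4) {
  if (is.null(n)) n <- sample(2:5, 1)
  A <- matrix(stats::rnorm(n * n, 0, coupling_sd), n, n)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 0.9) A <- A * (0.85 / rho)
  W <- matrix(stats::rnorm(n * n), n, n)
  Se <- crossprod(W) / n + diag(n) * 0.1
  phidnet:::new_mvar_system(A, Se)
}

two_node <- function(a, c, s = 0.2) make_two_node_system(a, c, s)
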
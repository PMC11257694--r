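# Stationary VAR(1) systems: x_t = A x_{t-1} + eps_t, eps_t ~ N(0, Sigma_eps).
# These are the synthetic stand-ins for parcellated fMRI timeseries: coupling
# (A) drives synergy, correlated innovations (Sigma_eps) drive redundancy.

new_mvar_system <- function(A, noise_cov, region_ids = NULL) {
  stopifnot(is_square(A), is_square(noise_cov), nrow(A) == nrow(noise_cov))
  n <- nrow(A)
  region_ids <- region_ids %||% paste0("R", seq_len(n))
  stopifnot(length(region_ids) == n)
  noise_cov <- symmetrize(noise_cov)
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("noise_cov must be symmetric positive definite", call. = FALSE)
  }
  rho <- spectral_radius(A)
  if (rho >= 1) {
    stop("stationarity error: spectral radius of A is ", signif(rho, 4),
         " (must be < 1)", call. = FALSE)
  }
  dimnames(A) <- list(region_ids, region_ids)
  dimnames(noise_cov) <- list(region_ids, region_ids)
  structure(
    list(A = A, noise_cov = noise_cov, region_ids = region_ids),
    class = "mvar_system"
  )
}

#' @export
print.mvar_system <- function(x, ...) {
  cat("<mvar_system> ", length(x$region_ids), " regions, spectral radius ",
      signif(spectral_radius(x$A), 4), "\n", sep = "")
  invisible(x)
}

#' Two-node coupled autoregressive system
#'
#' Builds the canonical two-parameter system used to illustrate how coupling
#' and common noise shape information dynamics: cross-coupling `a` between the
#' two nodes (raising `a` increases synergy) and innovation-noise correlation
#' `c` (raising `c` floods the pair with common noise and increases
#' redundancy). The transition matrix is
#' `A = [[s, a], [a, s]]` with self-coupling `s`, and the innovation
#' covariance is `[[1, c], [c, 1]]`.
#'
#' @param a Cross-coupling in `[0, 1)`.
#' @param c Innovation-noise correlation in `(-1, 1)`.
#' @param s Self-coupling (default 0.2); `|s| + |a|` must stay below 1.
#' @return An `mvar_system`.
#' @export
#' @examples
#' sys <- make_two_node_system(a = 0.4, c = 0.2)
#' analytic_stationary_cov(sys)
make_two_node_system <- function(a, c, s = 0.2) {
  stopifnot(is.numeric(a), length(a) == 1, is.numeric(c), length(c) == 1)
  if (abs(c) >= 1) {
    stop("invalid noise correlation: |c| must be < 1, got ", c, call. = FALSE)
  }
  A <- matrix(c(s, a, a, s), 2, 2)
  Se <- matrix(c(1, c, c, 1), 2, 2)
  new_mvar_system(A, Se, c("R1", "R2"))
}

#' Block-modular autoregressive system
#'
#' Generates a VAR(1) system whose coupling matrix has dense within-module
#' blocks and sparse between-module entries, with innovation noise correlated
#' inside modules -- a synthetic analogue of resting-state-network modular
#' structure. Entry magnitudes are mildly randomised (deterministically, given
#' `seed`) so modules are heterogeneous. If the implied spectral radius
#' exceeds `target_radius` the coupling matrix is rescaled to it.
#'
#' @param n_nodes Number of regions.
#' @param module_sizes Integer vector summing to `n_nodes`.
#' @param within_coupling Magnitude of within-module cross-coupling.
#' @param between_coupling Magnitude of between-module coupling.
#' @param noise_corr_within Innovation correlation inside modules.
#' @param seed Integer seed controlling the randomised magnitudes.
#' @param self_coupling Diagonal of `A` (default 0.2).
#' @param between_density Fraction of between-module entries that are
#'   non-zero (default 0.5).
#' @param target_radius Spectral radius to rescale to when exceeded
#'   (default 0.8).
#' @return A list with elements `system` (an `mvar_system`) and `partition`
#'   (a tibble with columns `region` and `module`).
#' @export
#' @examples
#' ms <- make_modular_system(6, c(3, 3), within_coupling = 0.3,
#'                           between_coupling = 0, noise_corr_within = 0,
#'                           seed = 1)
#' ms$partition
make_modular_system <- function(n_nodes, module_sizes,
                                within_coupling = 0.2,
                                between_coupling = 0.05,
                                noise_corr_within = 0.3,
                                seed = NULL,
                                self_coupling = 0.2,
                                between_density = 0.5,
                                target_radius = 0.8) {
  if (sum(module_sizes) != n_nodes) {
    stop("module_sizes must sum to n_nodes (", sum(module_sizes), " != ",
         n_nodes, ")", call. = FALSE)
  }
  module <- rep(seq_along(module_sizes), module_sizes)
  with_seed(seed, {
    same <- outer(module, module, `==`)
    off <- !diag(n_nodes)
    A <- matrix(0, n_nodes, n_nodes)
    wiggle <- function(k) stats::runif(k, 0.75, 1.25)
    idx_w <- which(same & off)
    A[idx_w] <- within_coupling * wiggle(length(idx_w))
    idx_b <- which(!same)
    keep <- stats::runif(length(idx_b)) < between_density
    A[idx_b[keep]] <- between_coupling * wiggle(sum(keep))
    diag(A) <- self_coupling
    rho <- spectral_radius(A)
    if (rho > target_radius) A <- A * (target_radius / rho)
    Se <- matrix(0, n_nodes, n_nodes)
    Se[same & off] <- noise_corr_within
    diag(Se) <- 1
    region_ids <- paste0("R", seq_len(n_nodes))
    list(
      system = new_mvar_system(A, Se, region_ids),
      partition = tibble::tibble(region = region_ids,
                                 module = paste0("M", module))
    )
  })
}

#' Analytic stationary covariance of a VAR(1) system
#'
#' Solves the discrete Lyapunov identity
#' `Sigma0 = A Sigma0 A' + Sigma_eps` (via vectorisation) for the
#' contemporaneous covariance, and derives the lag-`tau` cross-covariance
#' `Sigma_tau = Sigma0 (A')^tau`, whose entry `(i, j)` is
#' `Cov(x_i(t - tau), x_j(t))`. This is the exact population model against
#' which sample estimators can be validated.
#'
#' @param system An `mvar_system`.
#' @param tau Positive integer lag (default 1).
#' @return A `lagged_gaussian_model` (see [estimate_lagged_model()]) with
#'   `n_samples_used = 0` marking it analytic.
#' @export
analytic_stationary_cov <- function(system, tau = 1) {
  stopifnot(inherits(system, "mvar_system"), tau >= 1, tau == round(tau))
  A <- system$A
  n <- nrow(A)
  rho <- spectral_radius(A)
  if (rho >= 1) {
    stop("stationarity error: spectral radius ", signif(rho, 4), call. = FALSE)
  }
  vec_sigma0 <- solve(diag(n * n) - kronecker(A, A),
                      as.vector(system$noise_cov))
  sigma0 <- symmetrize(matrix(vec_sigma0, n, n))
  sigma_tau <- sigma0 %*% t(mat_pow(A, tau))
  new_lagged_gaussian_model(sigma0, sigma_tau, tau = tau, n_samples_used = 0L,
                            region_ids = system$region_ids)
}

#' Simulate a VAR(1) system
#'
#' Draws `x_t = A x_{t-1} + eps_t` with Gaussian innovations, discarding an
#' initial burn-in so the returned samples are (approximately) stationary.
#'
#' @param system An `mvar_system`.
#' @param n_timepoints Number of samples to return (rows).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param burn_in Initial samples discarded (default 100).
#' @return A numeric matrix, timepoints x regions, with region ids as column
#'   names.
#' @export
#' @examples
#' sys <- make_two_node_system(0.3, 0.2)
#' ts <- simulate_mvar(sys, 500, seed = 1)
simulate_mvar <- function(system, n_timepoints, seed = NULL, burn_in = 100) {
  stopifnot(inherits(system, "mvar_system"))
  if (n_timepoints <= 0) stop("n_timepoints must be positive", call. = FALSE)
  A <- system$A
  n <- nrow(A)
  R <- chol(system$noise_cov)
  total <- n_timepoints + burn_in
  with_seed(seed, {
    eps <- matrix(stats::rnorm(total * n), total, n) %*% R
    x <- matrix(0, total, n)
    x[1, ] <- eps[1, ]
    for (t in 2:total) x[t, ] <- A %*% x[t - 1, ] + eps[t, ]
    out <- x[(burn_in + 1):total, , drop = FALSE]
    colnames(out) <- system$region_ids
    out
  })
}

#' Simulate a multi-subject, multi-condition dataset
#'
#' Each subject receives an individual coupling matrix: the base `A` plus
#' independent Gaussian jitter on its non-zero entries (innovation covariance
#' is shared across subjects, so redundancy structure is fixed). In
#' non-baseline conditions the coupling on `effect_edges` is multiplied by
#' `effect_scale` (1 = no effect). Systems destabilised by jitter are rescaled
#' to spectral radius 0.95 with a warning. With a paired design every subject
#' appears in every condition (same jittered system); with an unpaired design
#' each condition gets its own subjects.
#'
#' @param base An `mvar_system`.
#' @param n_subjects Subjects per condition.
#' @param conditions Character vector of condition labels; the first is the
#'   baseline.
#' @param effect_edges Two-column matrix or data frame of region index pairs
#'   (both coupling directions are scaled), or `NULL`.
#' @param effect_scale Multiplier applied to coupling on `effect_edges` in
#'   non-baseline conditions (default 1.5; 1 disables the effect).
#' @param subject_jitter SD of the additive Gaussian jitter on non-zero
#'   entries of `A` (default 0.02).
#' @param n_timepoints Timepoints per scan.
#' @param design `"paired"` or `"unpaired"`.
#' @param seed Integer seed; per-subject seeds are derived from it and logged
#'   in the output.
#' @param burn_in Passed to [simulate_mvar()].
#' @return A `group_dataset`: a tibble with columns `subject_id`, `condition`,
#'   `seed` and a list-column `ts` of timeseries matrices; attributes `design`
#'   and `base_system`.
#' @export
simulate_group_dataset <- function(base, n_subjects,
                                   conditions = c("baseline", "effect"),
                                   effect_edges = NULL, effect_scale = 1.5,
                                   subject_jitter = 0.02, n_timepoints = 1000,
                                   design = c("paired", "unpaired"),
                                   seed = NULL, burn_in = 100) {
  stopifnot(inherits(base, "mvar_system"))
  design <- match.arg(design)
  if (length(conditions) == 0) stop("conditions list is empty", call. = FALSE)
  if (n_subjects <= 0) stop("n_subjects must be >= 1", call. = FALSE)
  if (effect_scale < 0) stop("effect_scale must be >= 0", call. = FALSE)
  n <- nrow(base$A)
  if (!is.null(effect_edges)) {
    effect_edges <- as.matrix(effect_edges)[, 1:2, drop = FALSE]
    if (any(effect_edges < 1) || any(effect_edges > n)) {
      stop("effect edges outside node range 1..", n, call. = FALSE)
    }
  }
  n_units <- if (design == "paired") n_subjects else n_subjects * length(conditions)
  seeds <- child_seeds(seed, n_units + 1)
  jitter_seed <- seeds[n_units + 1]

  jittered <- with_seed(jitter_seed, {
    lapply(seq_len(n_units), function(k) {
      A <- base$A
      nz <- A != 0
      A[nz] <- A[nz] + stats::rnorm(sum(nz), 0, subject_jitter)
      A
    })
  })

  apply_effect <- function(A, condition) {
    if (condition == conditions[1] || is.null(effect_edges) ||
        effect_scale == 1) {
      return(A)
    }
    for (r in seq_len(nrow(effect_edges))) {
      i <- effect_edges[r, 1]; j <- effect_edges[r, 2]
      A[i, j] <- A[i, j] * effect_scale
      A[j, i] <- A[j, i] * effect_scale
    }
    A
  }

  stabilise <- function(A) {
    rho <- spectral_radius(A)
    if (rho >= 0.95) {
      warning("jittered system rescaled from spectral radius ",
              signif(rho, 4), " to 0.95", call. = FALSE)
      A <- A * (0.95 / rho)
    }
    A
  }

  rows <- list()
  unit <- 0
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    for (s in seq_len(n_subjects)) {
      if (design == "paired") {
        u <- s
        sid <- sprintf("sub-%02d", s)
      } else {
        u <- (ci - 1) * n_subjects + s
        sid <- sprintf("sub-%s-%02d", cond, s)
      }
      A_s <- stabilise(apply_effect(jittered[[u]], cond))
      sys_s <- new_mvar_system(A_s, base$noise_cov, base$region_ids)
      # paired subjects get distinct noise streams per condition
      sim_seed <- (as.numeric(seeds[u]) + ci * 7919) %% .Machine$integer.max
      ts <- simulate_mvar(sys_s, n_timepoints, seed = sim_seed,
                          burn_in = burn_in)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sid, condition = cond, seed = sim_seed, ts = list(ts)
      )
      unit <- unit + 1
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "design") <- design
  attr(out, "base_system") <- base
  attr(out, "effect") <- list(edges = effect_edges, scale = effect_scale)
  class(out) <- c("group_dataset", class(out))
  out
}
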
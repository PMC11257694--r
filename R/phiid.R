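# Integrated information decomposition (MMI variant) for pairs of regions.
#
# For a pair (i, j) the joint Gaussian vector is
#   (x_i(t-tau), x_j(t-tau), x_i(t), x_j(t))
# and the quantities reported are:
#   tdmi       I(past pair; future pair)                 (time-delayed MI)
#   redundancy min of the four single-past -> single-future MIs
#   synergy    tdmi - max_a I(x_a past; joint future)
#   phi_wms    tdmi - I(x_i past; x_i future) - I(x_j past; x_j future)
#              ("whole-minus-sum" integrated information; can be negative
#               in redundancy-dominated systems)
#   phi_r      phi_wms + redundancy (revised integrated information,
#              non-negative by construction)
# plus the forward-PID atoms with the joint future as target.

# 4x4 past/future covariance for a pair, ordered (p_i, p_j, f_i, f_j).
pair_joint_cov <- function(model, i, j) {
  S0 <- model$sigma0
  L <- model$sigma_tau
  idx <- c(i, j)
  rbind(
    cbind(S0[idx, idx, drop = FALSE], L[idx, idx, drop = FALSE]),
    cbind(t(L[idx, idx, drop = FALSE]), S0[idx, idx, drop = FALSE])
  )
}

#' Integrated information atoms for one pair of regions
#'
#' Computes time-delayed mutual information, persistent redundancy and
#' synergy (MMI integrated information decomposition), whole-minus-sum
#' integrated information and its revised non-negative form `phi_r`, together
#' with the forward-PID atoms, for the pair `(i, j)` of a
#' [lagged Gaussian model][estimate_lagged_model]. All values in nats.
#'
#' @param model A `lagged_gaussian_model` (analytic or estimated).
#' @param i,j Distinct region indices or names.
#' @return A one-row tibble: `region_i`, `region_j`, `tdmi`, `redundancy`,
#'   `synergy`, `phi_wms`, `phi_r`, `unique_x`, `unique_y`.
#' @export
#' @examples
#' sys <- make_two_node_system(a = 0.1, c = 0.9)
#' phiid_atoms_pair(analytic_stationary_cov(sys), 1, 2)
phiid_atoms_pair <- function(model, i, j) {
  stopifnot(inherits(model, "lagged_gaussian_model"))
  ids <- model$region_ids
  if (is.character(i)) i <- match(i, ids)
  if (is.character(j)) j <- match(j, ids)
  if (is.na(i) || is.na(j) || i == j) {
    stop("need two distinct, valid regions", call. = FALSE)
  }
  J <- tryCatch(
    condition_cov(pair_joint_cov(model, i, j),
                  what = paste0("pair (", ids[i], ", ", ids[j], ") covariance")),
    error = function(e) stop(conditionMessage(e), call. = FALSE)
  )
  p <- 1:2
  f <- 3:4
  tdmi <- gaussian_mi(J, p, f)
  mi_ss <- matrix(0, 2, 2) # single past a -> single future b
  for (a in 1:2) for (b in 1:2) mi_ss[a, b] <- gaussian_mi(J, a, 2 + b)
  mi_sf <- c(gaussian_mi(J, 1, f), gaussian_mi(J, 2, f))
  red <- min(mi_ss)
  syn <- tdmi - max(mi_sf)
  phi_wms <- tdmi - mi_ss[1, 1] - mi_ss[2, 2]
  red_fwd <- min(mi_sf)
  tibble::tibble(
    region_i = ids[i], region_j = ids[j],
    tdmi = tdmi, redundancy = red, synergy = syn,
    phi_wms = phi_wms, phi_r = phi_wms + red,
    unique_x = mi_sf[1] - red_fwd, unique_y = mi_sf[2] - red_fwd
  )
}

# Closed-form vectorised atoms for all pairs i < j. Uses explicit 2x2/3x3
# determinants and a Schur complement for the 4x4, so a whole matrix of pairs
# costs a handful of vector operations. Pairs whose determinants are not
# comfortably positive are recomputed through the conditioned scalar route.
phiid_atoms_all_pairs <- function(model) {
  S0 <- model$sigma0
  L <- model$sigma_tau
  n <- nrow(S0)
  pr <- which(upper.tri(S0), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  s11 <- S0[cbind(i, i)]; s22 <- S0[cbind(j, j)]; s12 <- S0[cbind(i, j)]
  lii <- L[cbind(i, i)]; lij <- L[cbind(i, j)]
  lji <- L[cbind(j, i)]; ljj <- L[cbind(j, j)]

  det2 <- s11 * s22 - s12^2
  # I(p_a; f_b) for the four single-single combinations
  r2 <- cbind(lii^2 / (s11 * s11), lij^2 / (s11 * s22),
              lji^2 / (s22 * s11), ljj^2 / (s22 * s22))
  mi_ss <- -0.5 * log1p(-r2) # -(1/2) log(1 - r^2)
  # 3x3 determinants for (p_a, f_i, f_j)
  det3_i <- s11 * det2 - lii * (lii * s22 - s12 * lij) +
    lij * (lii * s12 - s11 * lij)
  det3_j <- s22 * det2 - lji * (lji * s22 - s12 * ljj) +
    ljj * (lji * s12 - s11 * ljj)
  mi_if <- 0.5 * (log(s11) + log(det2) - log(det3_i))
  mi_jf <- 0.5 * (log(s22) + log(det2) - log(det3_j))
  # Schur complement of the future block in the 4x4
  b11 <- (lii * s22 - lij * s12) / det2
  b12 <- (lij * s11 - lii * s12) / det2
  b21 <- (lji * s22 - ljj * s12) / det2
  b22 <- (ljj * s11 - lji * s12) / det2
  t11 <- b11 * lii + b12 * lij
  t12 <- b11 * lji + b12 * ljj
  t22 <- b21 * lji + b22 * ljj
  detS <- (s11 - t11) * (s22 - t22) - (s12 - t12)^2
  tdmi <- 0.5 * (log(det2) - log(detS))

  red <- pmin(mi_ss[, 1], mi_ss[, 2], mi_ss[, 3], mi_ss[, 4])
  syn <- tdmi - pmax(mi_if, mi_jf)
  phi_wms <- tdmi - mi_ss[, 1] - mi_ss[, 4]
  phi_r <- phi_wms + red

  bad <- !(det2 > 0 & det3_i > 0 & det3_j > 0 & detS > 0 &
             rowSums(r2 < 1) == 4 & is.finite(tdmi))
  out <- list(i = i, j = j, tdmi = tdmi, redundancy = red, synergy = syn,
              phi_wms = phi_wms, phi_r = phi_r, bad = which(bad))
  out
}

new_info_network <- function(values, measure, region_ids, tau,
                             n_samples_used = NA_integer_) {
  dimnames(values) <- list(region_ids, region_ids)
  structure(
    list(values = values, measure = measure, region_ids = region_ids,
         tau = tau, n_samples_used = n_samples_used),
    class = "info_network"
  )
}

#' @export
print.info_network <- function(x, ...) {
  cat("<info_network> ", x$measure, ": ", length(x$region_ids), " x ",
      length(x$region_ids), " regions, tau = ", x$tau, " (nats)\n", sep = "")
  invisible(x)
}

#' Pairwise information networks for all region pairs
#'
#' Evaluates the integrated-information atoms for every pair of regions and
#' returns one symmetric, zero-diagonal matrix per requested measure (the
#' whole-brain analogue of a region-by-region integrated information
#' matrix). Pairs are computed through a closed-form vectorised route;
#' numerically awkward pairs fall back to the conditioned per-pair route.
#' Under `on_error = "mask"` pairs that fail outright become `NA` with a
#' reported count instead of aborting.
#'
#' @param x A `lagged_gaussian_model`, or a timeseries matrix (timepoints x
#'   regions), in which case [estimate_lagged_model()] is applied first.
#' @param tau Lag, used only when `x` is a timeseries (default 1).
#' @param measures Subset of `"tdmi"`, `"redundancy"`, `"synergy"`,
#'   `"phi_wms"`, `"phi_r"`.
#' @param on_error `"abort"` (default) or `"mask"`.
#' @return A named list of `info_network` objects, one per measure.
#' @export
#' @examples
#' sys <- make_modular_system(6, c(3, 3), seed = 1)$system
#' nets <- pairwise_networks(analytic_stationary_cov(sys),
#'                           measures = c("synergy", "redundancy"))
#' nets$synergy
pairwise_networks <- function(x, tau = 1,
                              measures = c("tdmi", "redundancy", "synergy",
                                           "phi_wms", "phi_r"),
                              on_error = c("abort", "mask")) {
  on_error <- match.arg(on_error)
  measures <- match.arg(measures, several.ok = TRUE)
  model <- if (inherits(x, "lagged_gaussian_model")) x
           else estimate_lagged_model(x, tau = tau)
  n <- length(model$region_ids)
  if (n < 2) stop("need at least 2 regions", call. = FALSE)
  at <- phiid_atoms_all_pairs(model)
  # fall back to the conditioned scalar route where the fast path failed
  if (length(at$bad) > 0) {
    failed <- character(0)
    for (k in at$bad) {
      res <- tryCatch(phiid_atoms_pair(model, at$i[k], at$j[k]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        if (on_error == "abort") {
          stop("pair (", at$i[k], ", ", at$j[k], "): ",
               conditionMessage(res), call. = FALSE)
        }
        failed <- c(failed, paste0("(", at$i[k], ",", at$j[k], ")"))
        for (m in c("tdmi", "redundancy", "synergy", "phi_wms", "phi_r")) {
          at[[m]][k] <- NA_real_
        }
      } else {
        for (m in c("tdmi", "redundancy", "synergy", "phi_wms", "phi_r")) {
          at[[m]][k] <- res[[m]]
        }
      }
    }
    if (length(failed) > 0) {
      message(length(failed), " pair(s) masked as missing: ",
              paste(failed, collapse = " "))
    }
  }
  out <- lapply(measures, function(m) {
    M <- matrix(0, n, n)
    M[cbind(at$i, at$j)] <- at[[m]]
    M[cbind(at$j, at$i)] <- at[[m]]
    new_info_network(M, m, model$region_ids, model$tau,
                     model$n_samples_used)
  })
  names(out) <- measures
  out
}

#' Element-wise average of information networks
#'
#' Averages matrices across subjects (same measure, regions and lag
#' required). Masked (`NA`) entries are averaged over the subjects where
#' they are available.
#'
#' @param networks List of `info_network` objects.
#' @return An `info_network` holding the group average.
#' @export
group_average <- function(networks) {
  if (length(networks) == 0) stop("empty network list", call. = FALSE)
  stopifnot(all(vapply(networks, inherits, TRUE, "info_network")))
  ref <- networks[[1]]
  for (nw in networks[-1]) {
    if (!identical(nw$measure, ref$measure) ||
        !identical(nw$region_ids, ref$region_ids) ||
        !identical(nw$tau, ref$tau)) {
      stop("networks must share measure, region set and tau", call. = FALSE)
    }
  }
  vals <- lapply(networks, `[[`, "values")
  sum_m <- Reduce(`+`, lapply(vals, function(v) ifelse(is.na(v), 0, v)))
  cnt <- Reduce(`+`, lapply(vals, function(v) !is.na(v)))
  avg <- sum_m / cnt
  avg[cnt == 0] <- NA_real_
  if (any(cnt < length(networks) & cnt > 0)) {
    message("averaged over available subjects at ",
            sum(cnt < length(networks) & cnt > 0) / 2, " masked pair(s)")
  }
  new_info_network(avg, ref$measure, ref$region_ids, ref$tau)
}
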
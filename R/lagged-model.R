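# Second-order summary of a stationary Gaussian process: contemporaneous and
# lag-tau covariances. Everything downstream (MI, PID, integrated
# information) is a function of this object only.

new_lagged_gaussian_model <- function(sigma0, sigma_tau, tau, n_samples_used,
                                      region_ids = NULL) {
  stopifnot(is_square(sigma0), is_square(sigma_tau),
            nrow(sigma0) == nrow(sigma_tau))
  n <- nrow(sigma0)
  region_ids <- region_ids %||% colnames(sigma0) %||% paste0("R", seq_len(n))
  sigma0 <- symmetrize(sigma0)
  dimnames(sigma0) <- list(region_ids, region_ids)
  dimnames(sigma_tau) <- list(region_ids, region_ids)
  structure(
    list(sigma0 = sigma0, sigma_tau = sigma_tau, tau = as.integer(tau),
         n_samples_used = as.integer(n_samples_used),
         region_ids = region_ids),
    class = "lagged_gaussian_model"
  )
}

#' @export
print.lagged_gaussian_model <- function(x, ...) {
  src <- if (x$n_samples_used == 0) "analytic"
         else paste0(x$n_samples_used, " sample pairs")
  cat("<lagged_gaussian_model> ", length(x$region_ids), " regions, tau = ",
      x$tau, " (", src, ")\n", sep = "")
  invisible(x)
}

#' Estimate contemporaneous and lagged covariances from a timeseries
#'
#' Removes the per-region mean, aligns the `T - tau` past/future sample
#' pairs, and estimates the contemporaneous covariance `sigma0` (pooled over
#' the past and future segments) and the lag-`tau` cross-covariance
#' `sigma_tau`, whose entry `(i, j)` is `Cov(x_i(t - tau), x_j(t))`. A single
#' shared normalisation `T - tau - 1` is used for all blocks.
#'
#' @param ts Numeric matrix, timepoints x regions (region ids as column
#'   names), as produced by [simulate_mvar()] or [read_timeseries()].
#' @param tau Positive integer lag in samples (default 1).
#' @return A `lagged_gaussian_model`.
#' @export
estimate_lagged_model <- function(ts, tau = 1) {
  ts <- as.matrix(ts)
  stopifnot(is.numeric(ts), tau >= 1, tau == round(tau))
  T_ <- nrow(ts)
  if (T_ <= tau + 2) {
    stop("need n_timepoints > tau + 2 (got T = ", T_, ", tau = ", tau, ")",
         call. = FALSE)
  }
  vars <- apply(ts, 2, stats::var)
  if (any(vars == 0)) {
    bad <- colnames(ts)[vars == 0] %||% which(vars == 0)
    stop("degenerate-input error: constant (zero-variance) region(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x <- sweep(ts, 2, colMeans(ts))
  m <- T_ - tau
  P <- x[seq_len(m), , drop = FALSE]
  F_ <- x[(tau + 1):T_, , drop = FALSE]
  denom <- m - 1
  sigma0 <- (crossprod(P) + crossprod(F_)) / (2 * denom)
  sigma_tau <- crossprod(P, F_) / denom
  new_lagged_gaussian_model(sigma0, sigma_tau, tau = tau, n_samples_used = m,
                            region_ids = colnames(ts))
}
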
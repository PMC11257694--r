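# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs `code` on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Draw per-unit child seeds (< 2^31) from a parent seed, reproducibly.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

spectral_radius <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

# Integer matrix power by repeated squaring (tau is small in practice).
mat_pow <- function(A, k) {
  stopifnot(k >= 0, k == round(k))
  n <- nrow(A)
  out <- diag(n)
  P <- A
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% P
    k <- k %/% 2
    if (k > 0) P <- P %*% P
  }
  out
}

# log-determinant of a symmetric positive definite matrix via Cholesky.
# Returns NA (no error) if the factorisation fails; callers decide policy.
chol_logdet <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  2 * sum(log(diag(R)))
}

symmetrize <- function(S) (S + t(S)) / 2

# Covariance conditioning: if the smallest eigenvalue is below
# 1e-10 x largest, add a single diagonal jitter of 1e-10 x mean variance.
# A matrix still degenerate after jitter signals truly redundant signals.
condition_cov <- function(S, what = "covariance") {
  S <- symmetrize(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(ev, 0)
  if (min(ev) >= tol && min(ev) > 0) return(S)
  S <- S + diag(1e-10 * mean(diag(S)), nrow(S))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || min(ev) < 1e-10 * max(ev)) {
    stop("degenerate-input error: ", what,
         " is singular beyond conditioning tolerance", call. = FALSE)
  }
  S
}

# Average ranks ascending (1 = lowest); ties get fractional ranks so that
# rank differences never depend on input ordering.
rank_asc <- function(x) rank(x, ties.method = "average")

is_square <- function(M) is.matrix(M) && nrow(M) == ncol(M)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert information values from nats to bits
#'
#' All information quantities in phidnet are reported in nats (natural
#' logarithm). This helper rescales to bits for display.
#'
#' @param x Numeric vector/matrix of values in nats.
#' @return `x / log(2)`.
#' @export
#' @examples
#' nats_to_bits(log(2)) # = 1 bit
nats_to_bits <- function(x) x / log(2)
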
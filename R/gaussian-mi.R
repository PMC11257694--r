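# Gaussian mutual information and the minimum-mutual-information PID.

#' Gaussian mutual information between two blocks of a joint covariance
#'
#' For jointly Gaussian variables partitioned into sets `U` and `V`,
#' `I(U; V) = (log det S_U + log det S_V - log det S_UV) / 2` in nats.
#' Near-singular covariances receive one diagonal jitter of
#' `1e-10 x mean variance`; truly singular inputs (e.g. a duplicated
#' variable shared between the blocks) raise a degenerate-input error.
#'
#' @param joint_cov Covariance matrix over all variables in `U` and `V`.
#' @param u,v Integer (or name) indices of the two blocks; must be disjoint.
#' @return Mutual information in nats (non-negative up to roundoff).
#' @export
#' @examples
#' S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
#' gaussian_mi(S, 1, 2) # -log(1 - 0.25) / 2
gaussian_mi <- function(joint_cov, u, v) {
  stopifnot(is_square(joint_cov))
  if (is.character(u)) u <- match(u, colnames(joint_cov))
  if (is.character(v)) v <- match(v, colnames(joint_cov))
  if (length(intersect(u, v)) > 0) {
    stop("degenerate-input error: blocks U and V overlap", call. = FALSE)
  }
  S <- condition_cov(joint_cov[c(u, v), c(u, v), drop = FALSE],
                     what = "joint covariance (U,V)")
  iu <- seq_along(u)
  iv <- length(u) + seq_along(v)
  ld_u <- chol_logdet(S[iu, iu, drop = FALSE])
  ld_v <- chol_logdet(S[iv, iv, drop = FALSE])
  ld_uv <- chol_logdet(S)
  for (nm in c("ld_u" = ld_u, "ld_v" = ld_v, "ld_uv" = ld_uv)) {
    if (is.na(nm)) {
      stop("degenerate-input error: singular covariance block", call. = FALSE)
    }
  }
  0.5 * (ld_u + ld_v - ld_uv)
}

#' Minimum-mutual-information partial information decomposition
#'
#' Decomposes the information two Gaussian source blocks `X` and `Y` carry
#' about a target block `Z` into redundancy, two unique atoms and synergy,
#' using the minimum-mutual-information redundancy
#' `Red = min(I(X;Z), I(Y;Z))`. The four atoms satisfy, exactly:
#' `Red + Un_X + Un_Y + Syn = I(X,Y; Z)`, and by construction the weaker
#' source's unique atom is zero.
#'
#' @param joint_cov Covariance over all variables involved.
#' @param x,y Disjoint index sets of the two sources.
#' @param z Index set of the target.
#' @return A one-row tibble with columns `redundancy`, `unique_x`,
#'   `unique_y`, `synergy`, `mi_x`, `mi_y`, `mi_xy` (all nats).
#' @export
pid_mmi <- function(joint_cov, x, y, z) {
  if (length(intersect(x, y)) > 0) {
    stop("source sets X and Y must be disjoint", call. = FALSE)
  }
  mi_x <- gaussian_mi(joint_cov, x, z)
  mi_y <- gaussian_mi(joint_cov, y, z)
  mi_xy <- gaussian_mi(joint_cov, c(x, y), z)
  red <- min(mi_x, mi_y)
  tibble::tibble(
    redundancy = red,
    unique_x = mi_x - red,
    unique_y = mi_y - red,
    synergy = mi_xy - mi_x - mi_y + red,
    mi_x = mi_x, mi_y = mi_y, mi_xy = mi_xy
  )
}
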
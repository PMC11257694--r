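# Synergy-redundancy rank gradient and the synergistic workspace.
#
# Regions are ranked (ascending: 1 = lowest) by nodal strength separately on
# the synergy and redundancy networks; the per-region gradient is
# rank_syn - rank_red. The gradient is relative: a positive value says the
# region's balance tilts toward synergy compared with the rest of the brain,
# not that its synergy exceeds its redundancy in absolute terms. Regions
# with a strictly positive gradient form the synergistic workspace.

#' Nodal strength of an information network
#'
#' `strength_i = sum_j value(i, j)` with the (zero) diagonal excluded.
#' Masked (`NA`) entries are excluded from the sum with a note.
#'
#' @param network An `info_network`.
#' @return A tibble with columns `region` and `strength`.
#' @export
node_strength <- function(network) {
  stopifnot(inherits(network, "info_network"))
  V <- network$values
  if (anyNA(V)) {
    message(sum(is.na(V[upper.tri(V)])),
            " masked pair(s) excluded from strength sums")
  }
  diag(V) <- 0
  tibble::tibble(region = network$region_ids,
                 strength = unname(rowSums(V, na.rm = TRUE)))
}

#' Synergy-minus-redundancy rank gradient
#'
#' Ranks regions by strength on each network (ascending, average ranks on
#' ties) and takes the difference `rank_syn - rank_red`. Sums to zero over
#' regions whenever ranks are untied.
#'
#' @param strength_syn,strength_red Strength tables from [node_strength()]
#'   (or named numeric vectors) over the same regions.
#' @return A tibble: `region`, `strength_syn`, `strength_red`, `rank_syn`,
#'   `rank_red`, `gradient`.
#' @export
rank_gradient <- function(strength_syn, strength_red) {
  as_tbl <- function(x, nm) {
    if (inherits(x, "data.frame")) {
      stats::setNames(tibble::as_tibble(x)[, c("region", "strength")],
                      c("region", nm))
    } else {
      tibble::tibble(region = names(x) %||% paste0("R", seq_along(x)),
                     "{nm}" := as.numeric(x))
    }
  }
  s <- dplyr::inner_join(as_tbl(strength_syn, "strength_syn"),
                         as_tbl(strength_red, "strength_red"),
                         by = "region")
  if (nrow(s) != length(unique(s$region)) ||
      nrow(s) < max(NROW(strength_syn), NROW(strength_red))) {
    stop("synergy and redundancy strengths must cover the same regions",
         call. = FALSE)
  }
  dplyr::mutate(s,
                rank_syn = rank_asc(.data$strength_syn),
                rank_red = rank_asc(.data$strength_red),
                gradient = .data$rank_syn - .data$rank_red)
}

#' Synergistic-workspace membership
#'
#' Regions with a strictly positive rank gradient belong to the workspace;
#' zero-gradient regions are excluded. Percentile cuts can be used instead
#' of the sign rule via `rule`.
#'
#' @param gradient A table from [rank_gradient()] (needs columns `region`
#'   and `gradient`) or a named numeric vector of gradients.
#' @param rule `"sign"` (default: gradient > 0) or `"percentile"`.
#' @param percentile Cut point in (0, 1) when `rule = "percentile"`:
#'   workspace = regions with gradient above that quantile.
#' @return The input tibble with a logical `workspace` column appended.
#' @export
workspace_membership <- function(gradient, rule = c("sign", "percentile"),
                                 percentile = 0.5) {
  rule <- match.arg(rule)
  if (!inherits(gradient, "data.frame")) {
    gradient <- tibble::tibble(
      region = names(gradient) %||% paste0("R", seq_along(gradient)),
      gradient = as.numeric(gradient))
  }
  g <- gradient$gradient
  ws <- if (rule == "sign") g > 0
        else g > stats::quantile(g, percentile, names = FALSE)
  if (!any(ws)) {
    warning("empty workspace: no region has a positive rank gradient",
            call. = FALSE)
  }
  dplyr::mutate(gradient, workspace = ws)
}

#' Per-region profile: strengths, gradient, workspace, roles
#'
#' One-call wrapper running [node_strength()], [rank_gradient()] and
#' [workspace_membership()] on a synergy/redundancy network pair, and -- when
#' a module partition is supplied -- [participation_coefficient()] and
#' [classify_workspace_roles()] as well.
#'
#' @param syn,red `info_network` objects (typically group averages) for
#'   synergy and redundancy.
#' @param partition Optional module partition (tibble `region`, `module`, or
#'   a named vector); enables participation coefficients and
#'   gateway/broadcaster roles.
#' @param rule,percentile Passed to [workspace_membership()].
#' @return A `node_profiles` tibble: `region`, `strength_syn`,
#'   `strength_red`, `rank_syn`, `rank_red`, `gradient`, `workspace`, and
#'   with a partition also `pc_syn`, `pc_red`, `pc_rank_gradient`, `role`.
#' @export
#' @examples
#' ms <- make_modular_system(6, c(3, 3), seed = 1)
#' nets <- pairwise_networks(analytic_stationary_cov(ms$system),
#'                           measures = c("synergy", "redundancy"))
#' node_profiles(nets$synergy, nets$redundancy, ms$partition)
node_profiles <- function(syn, red, partition = NULL,
                          rule = c("sign", "percentile"), percentile = 0.5) {
  stopifnot(inherits(syn, "info_network"), inherits(red, "info_network"))
  prof <- workspace_membership(
    rank_gradient(node_strength(syn), node_strength(red)),
    rule = match.arg(rule), percentile = percentile)
  if (!is.null(partition)) {
    pc_s <- participation_coefficient(syn, partition)
    pc_r <- participation_coefficient(red, partition)
    prof <- dplyr::left_join(
      prof,
      dplyr::inner_join(
        stats::setNames(pc_s, c("region", "pc_syn")),
        stats::setNames(pc_r, c("region", "pc_red")), by = "region"),
      by = "region")
    prof <- classify_workspace_roles(prof)
  }
  class(prof) <- c("node_profiles", class(prof))
  prof
}
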
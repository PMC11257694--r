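# Participation coefficient against a module partition, and the
# gateway/broadcaster subdivision of workspace regions.

as_partition <- function(partition, region_ids) {
  if (inherits(partition, "data.frame")) {
    stopifnot(all(c("region", "module") %in% names(partition)))
    p <- stats::setNames(as.character(partition$module), partition$region)
  } else {
    p <- stats::setNames(as.character(partition),
                         names(partition) %||% region_ids)
  }
  missing <- setdiff(region_ids, names(p))
  if (length(missing) > 0) {
    stop("partition does not label region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p[region_ids]
}

#' Participation coefficient of each region
#'
#' `P_i = 1 - sum_s (kappa_is / k_i)^2`, where `kappa_is` is region `i`'s
#' strength of positive connections into module `s` (own module included)
#' and `k_i` its total positive strength. `P_i` is 0 when all of a region's
#' connections stay inside its own module and approaches `1 - 1/M` at equal
#' spread over all `M` modules. Negative entries (possible only for
#' whole-minus-sum networks) are excluded; regions with zero positive
#' strength get `P_i = 0` with a note.
#'
#' @param network An `info_network` (or a plain symmetric matrix with region
#'   names).
#' @param partition Module partition: tibble with columns `region`,
#'   `module`, or a named character vector.
#' @return A tibble with columns `region` and `pc`.
#' @export
participation_coefficient <- function(network, partition) {
  if (inherits(network, "info_network")) {
    V <- network$values
    ids <- network$region_ids
  } else {
    V <- as.matrix(network)
    ids <- colnames(V) %||% paste0("R", seq_len(ncol(V)))
  }
  stopifnot(is_square(V))
  mod <- as_partition(partition, ids)
  if (length(unique(mod)) < 2) {
    stop("partition must define at least 2 modules", call. = FALSE)
  }
  W <- V
  diag(W) <- 0
  W[is.na(W) | W < 0] <- 0
  # strength into each module: n x M
  mod_f <- factor(mod)
  agg <- W %*% stats::model.matrix(~ mod_f - 1)
  k <- rowSums(agg)
  pc <- ifelse(k > 0, 1 - rowSums((agg / pmax(k, .Machine$double.eps))^2), 0)
  if (any(k == 0)) {
    message(sum(k == 0), " region(s) with zero positive strength given P = 0")
  }
  tibble::tibble(region = ids, pc = as.numeric(pc))
}

#' Classify workspace regions into gateways and broadcasters
#'
#' Within the workspace only, regions are ranked (ascending, average-rank
#' ties) by their synergy- and redundancy-based participation coefficients;
#' `pc_rank_gradient = rank(pc_syn) - rank(pc_red)`. A positive gradient
#' marks a gateway (synergistic connections spread over many modules), a
#' negative one a broadcaster (redundant connections spread over many
#' modules), zero is unclassified. Non-workspace regions get role
#' `"non-workspace"`.
#'
#' @param profiles A tibble with columns `region`, `workspace`, `pc_syn`,
#'   `pc_red` (e.g. from [node_profiles()]).
#' @return The input with `pc_rank_gradient` and `role` columns appended.
#' @export
classify_workspace_roles <- function(profiles) {
  stopifnot(all(c("region", "workspace", "pc_syn", "pc_red")
                %in% names(profiles)))
  ws <- profiles$workspace
  if (!any(ws)) {
    warning("empty workspace: all regions classified non-workspace",
            call. = FALSE)
  }
  pc_grad <- rep(NA_real_, nrow(profiles))
  if (any(ws)) {
    pc_grad[ws] <- rank_asc(profiles$pc_syn[ws]) -
      rank_asc(profiles$pc_red[ws])
  }
  role <- dplyr::case_when(
    !ws ~ "non-workspace",
    pc_grad > 0 ~ "gateway",
    pc_grad < 0 ~ "broadcaster",
    TRUE ~ "unclassified"
  )
  dplyr::mutate(profiles, pc_rank_gradient = pc_grad, role = role)
}

#' Correlation between participation coefficients from two partitions
#'
#' Plain linear (Pearson) correlation between two per-region participation
#' coefficient vectors, e.g. from an a-priori and a data-driven partition.
#'
#' @param pc_a,pc_b Tibbles from [participation_coefficient()] or numeric
#'   vectors over the same regions.
#' @return The correlation coefficient.
#' @export
partition_agreement <- function(pc_a, pc_b) {
  getv <- function(x) if (inherits(x, "data.frame")) x$pc else as.numeric(x)
  a <- getv(pc_a)
  b <- getv(pc_b)
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: constant participation vector",
         call. = FALSE)
  }
  stats::cor(a, b)
}
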
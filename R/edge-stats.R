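# Edgewise condition contrasts and the network-based statistic (NBS).
#
# Subject-level edge data are held as an `edge_samples` object: a
# subjects x edges matrix over the vectorised upper triangle of a
# region x region network, with the region geometry attached so edge
# statistics can be folded back into matrices and connected components
# found on the region graph.

#' Collect subject-level networks into an edge-sample matrix
#'
#' @param x A list of `info_network` objects, a list of symmetric matrices,
#'   or a 3D array (region x region x subject).
#' @param subject_ids Optional subject identifiers (row names).
#' @return An `edge_samples` object: subjects x edges matrix of upper
#'   triangle values with region geometry attributes.
#' @export
as_edge_samples <- function(x, subject_ids = NULL) {
  if (is.array(x) && length(dim(x)) == 3) {
    x <- lapply(seq_len(dim(x)[3]), function(k) x[, , k])
  }
  if (inherits(x, "edge_samples")) return(x)
  stopifnot(is.list(x), length(x) > 0)
  mats <- lapply(x, function(m) {
    if (inherits(m, "info_network")) m$values else as.matrix(m)
  })
  n <- nrow(mats[[1]])
  stopifnot(all(vapply(mats, function(m) nrow(m) == n && ncol(m) == n, TRUE)))
  region_ids <- colnames(mats[[1]]) %||% paste0("R", seq_len(n))
  ut <- upper.tri(mats[[1]])
  X <- do.call(rbind, lapply(mats, function(m) m[ut]))
  rownames(X) <- subject_ids %||% names(x)
  structure(X, class = c("edge_samples", "matrix"),
            n_regions = n, region_ids = region_ids)
}

edge_geometry <- function(n) {
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  list(i = pr[, 1], j = pr[, 2])
}

edge_to_matrix <- function(v, n, region_ids = NULL) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- v
  M <- M + t(M)
  if (!is.null(region_ids)) dimnames(M) <- list(region_ids, region_ids)
  M
}

# Vectorised edge F-statistics. Unpaired: squared pooled-variance two-sample
# t. Paired: squared paired t on matched rows. Zero-variance edges get
# F = Inf when the means differ and 0 when they do not.
f_edges_unpaired <- function(Xa, Xb) {
  na <- nrow(Xa); nb <- nrow(Xb)
  ma <- colMeans(Xa); mb <- colMeans(Xb)
  va <- (colSums(Xa^2) - na * ma^2) / (na - 1)
  vb <- (colSums(Xb^2) - nb * mb^2) / (nb - 1)
  sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  num <- (mb - ma)^2
  f <- ifelse(sp > 0, num / (sp * (1 / na + 1 / nb)),
              ifelse(num > 0, Inf, 0))
  list(f = f, sign = sign(mb - ma))
}

f_edges_paired <- function(D) {
  n <- nrow(D)
  md <- colMeans(D)
  vd <- (colSums(D^2) - n * md^2) / (n - 1)
  f <- ifelse(vd > 0, n * md^2 / vd, ifelse(md != 0, Inf, 0))
  list(f = f, sign = sign(md))
}

#' Edgewise F contrast between two conditions
#'
#' Computes, independently per edge, a two-sided F score (the squared t
#' statistic: pooled-variance two-sample t for unpaired designs, paired t
#' for paired designs) and the direction of effect
#' `sign(mean_b - mean_a)`.
#'
#' @param a,b Subject-level edge data for the two conditions (anything
#'   [as_edge_samples()] accepts). Paired designs require matched row order
#'   and equal subject counts.
#' @param design `"unpaired"` or `"paired"`.
#' @return An `edge_contrast`: list with `f_matrix`, `sign_matrix`,
#'   `design`, `n_a`, `n_b`, `region_ids`.
#' @export
#' @examples
#' a <- lapply(1:3, function(k) {m <- matrix(k, 3, 3); diag(m) <- 0; m})
#' b <- lapply(4:6, function(k) {m <- matrix(k, 3, 3); diag(m) <- 0; m})
#' edgewise_f(a, b, design = "unpaired")$f_matrix[1, 2] # 13.5
edgewise_f <- function(a, b, design = c("unpaired", "paired")) {
  design <- match.arg(design)
  a <- as_edge_samples(a)
  b <- as_edge_samples(b)
  n <- attr(a, "n_regions")
  if (n != attr(b, "n_regions")) {
    stop("conditions measured on different region sets", call. = FALSE)
  }
  if (design == "paired" && nrow(a) != nrow(b)) {
    stop("paired design requires equal, matched subject lists",
         call. = FALSE)
  }
  res <- if (design == "paired") {
    f_edges_paired(unclass(b) - unclass(a))
  } else {
    f_edges_unpaired(unclass(a), unclass(b))
  }
  if (any(is.infinite(res$f))) {
    warning(sum(is.infinite(res$f)),
            " edge(s) with zero within-group variance and differing means",
            " set to F = Inf", call. = FALSE)
  }
  ids <- attr(a, "region_ids")
  structure(
    list(f_matrix = edge_to_matrix(res$f, n, ids),
         sign_matrix = edge_to_matrix(res$sign, n, ids),
         design = design, n_a = nrow(a), n_b = nrow(b),
         region_ids = ids),
    class = "edge_contrast"
  )
}

# Connected components of the supra-threshold graph. Returns a tibble of
# components plus the component id of every supra-threshold edge.
supra_components <- function(f, threshold, geo, n, measure) {
  supra <- which(f > threshold & !is.na(f))
  if (length(supra) == 0) {
    return(list(components = tibble::tibble(component_id = integer(),
                                            n_edges = integer(),
                                            statistic = double()),
                edge_idx = supra, edge_component = integer()))
  }
  g <- igraph::make_graph(rbind(geo$i[supra], geo$j[supra]), n = n,
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[geo$i[supra]]
  stat <- if (measure == "intensity") {
    tapply(f[supra], comp_of_edge, sum)
  } else {
    tapply(f[supra], comp_of_edge, length)
  }
  ord <- order(as.numeric(stat), decreasing = TRUE)
  ids_sorted <- as.integer(names(stat))[ord]
  remap <- stats::setNames(seq_along(ids_sorted), ids_sorted)
  list(
    components = tibble::tibble(
      component_id = seq_along(ids_sorted),
      n_edges = as.integer(tapply(f[supra], comp_of_edge, length)[as.character(ids_sorted)]),
      statistic = as.numeric(stat[as.character(ids_sorted)])),
    edge_idx = supra,
    edge_component = as.integer(remap[as.character(comp_of_edge)])
  )
}

max_component_stat <- function(f, threshold, geo, n, measure) {
  supra <- which(f > threshold & !is.na(f))
  if (length(supra) == 0) return(0)
  g <- igraph::make_graph(rbind(geo$i[supra], geo$j[supra]), n = n,
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[geo$i[supra]]
  if (measure == "intensity") {
    max(rowsum(f[supra], comp_of_edge))
  } else {
    max(tabulate(comp_of_edge))
  }
}

#' Network-based statistic (NBS)
#'
#' Familywise-error-corrected inference on edge contrasts: edges surviving
#' an a-priori F threshold form a supra-threshold graph whose connected
#' components are scored by intensity (sum of F) or extent (edge count);
#' component significance is assessed against a permutation null of the
#' maximum component score (group-label permutations for unpaired designs,
#' within-subject condition flips for paired ones). Permutation p-values
#' use the `(1 + b) / (1 + B)` estimator.
#'
#' @param a,b Subject-level edge data (see [as_edge_samples()]).
#' @param design `"unpaired"` or `"paired"`.
#' @param threshold A-priori edge F threshold (default 9).
#' @param component_measure `"intensity"` (default) or `"extent"`.
#' @param n_perm Number of permutations (default 5000, minimum 100).
#' @param alpha Component significance level (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return An `nbs_result`: threshold and settings, `components` tibble
#'   (`component_id`, `n_edges`, `statistic`, `p_value`), `edges` tibble
#'   (per supra-threshold edge: `region_i`, `region_j`, `f`, `sign`,
#'   `component_id`, `p_value`, `significant`), the significant-edge mask,
#'   the signed F-sum over significant edges, and the null maxima.
#' @export
nbs <- function(a, b, design = c("unpaired", "paired"), threshold = 9,
                component_measure = c("intensity", "extent"),
                n_perm = 5000, alpha = 0.05, seed = NULL) {
  design <- match.arg(design)
  component_measure <- match.arg(component_measure)
  stopifnot(threshold > 0)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (1 / (1 + n_perm) > alpha) {
    warning("n_perm too small to ever reach alpha = ", alpha, call. = FALSE)
  }
  a <- as_edge_samples(a)
  b <- as_edge_samples(b)
  contrast <- edgewise_f(a, b, design)
  n <- attr(a, "n_regions")
  geo <- edge_geometry(n)
  ut <- upper.tri(diag(n))
  f_obs <- contrast$f_matrix[ut]
  sgn <- contrast$sign_matrix[ut]
  obs <- supra_components(f_obs, threshold, geo, n, component_measure)

  Xa <- unclass(a); Xb <- unclass(b)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      f_p <- if (design == "paired") {
        flip <- sample(c(-1, 1), nrow(Xa), replace = TRUE)
        f_edges_paired((Xb - Xa) * flip)$f
      } else {
        pool <- rbind(Xa, Xb)
        idx <- sample.int(nrow(pool))
        f_edges_unpaired(pool[idx[seq_len(nrow(Xa))], , drop = FALSE],
                         pool[idx[-seq_len(nrow(Xa))], , drop = FALSE])$f
      }
      max_component_stat(f_p, threshold, geo, n, component_measure)
    }, numeric(1))
  })

  comps <- dplyr::mutate(
    obs$components,
    p_value = vapply(.data$statistic,
                     function(s) (1 + sum(null_max >= s)) / (1 + n_perm),
                     numeric(1)))
  ids <- contrast$region_ids
  edges <- tibble::tibble(
    region_i = ids[geo$i[obs$edge_idx]],
    region_j = ids[geo$j[obs$edge_idx]],
    f = f_obs[obs$edge_idx],
    sign = sgn[obs$edge_idx],
    component_id = obs$edge_component)
  edges <- dplyr::left_join(edges, comps[, c("component_id", "p_value")],
                            by = "component_id")
  edges$significant <- edges$p_value <= alpha
  sig_mask <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (any(edges$significant)) {
    ii <- geo$i[obs$edge_idx[edges$significant]]
    jj <- geo$j[obs$edge_idx[edges$significant]]
    sig_mask[cbind(ii, jj)] <- TRUE
    sig_mask[cbind(jj, ii)] <- TRUE
  }
  structure(
    list(contrast = contrast, threshold = threshold,
         component_measure = component_measure, n_perm = n_perm,
         alpha = alpha, seed = seed, components = comps, edges = edges,
         significant_edges = sig_mask,
         signed_f_sum = sum(edges$sign[edges$significant] *
                              edges$f[edges$significant]),
         null_max = null_max),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  nsig <- sum(x$components$p_value <= x$alpha)
  cat("<nbs_result> threshold F > ", x$threshold, " (",
      x$component_measure, "), ", nrow(x$components),
      " component(s), ", nsig, " significant at alpha = ", x$alpha,
      " [", x$n_perm, " permutations]\n", sep = "")
  if (nrow(x$components) > 0) print(x$components)
  invisible(x)
}

#' Per-condition edge samples of an information measure
#'
#' Computes one pairwise network per scan of a [simulate_group_dataset()]
#' result (or any tibble with `subject_id`, `condition` and a `ts`
#' list-column) and collects the requested measure into one
#' [edge-sample matrix][as_edge_samples] per condition.
#'
#' @param dataset A `group_dataset`.
#' @param measure One of `"tdmi"`, `"redundancy"`, `"synergy"`,
#'   `"phi_wms"`, `"phi_r"`.
#' @param tau Lag passed to [pairwise_networks()].
#' @return A named list of `edge_samples`, one per condition, subjects in
#'   the dataset's row order.
#' @export
edge_samples_by_condition <- function(dataset, measure = "phi_r", tau = 1) {
  stopifnot(all(c("subject_id", "condition", "ts") %in% names(dataset)))
  nets <- lapply(dataset$ts, function(ts)
    pairwise_networks(ts, tau = tau, measures = measure)[[measure]])
  lapply(split(seq_len(nrow(dataset)), dataset$condition), function(rows)
    as_edge_samples(nets[rows], subject_ids = dataset$subject_id[rows]))
}
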
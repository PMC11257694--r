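# Composite least-favourable-configuration test for effects shared across
# datasets. The edge statistic is the minimum of the per-dataset F scores;
# the null is sampled by reshuffling exactly one dataset (picked uniformly
# at random) per permutation and recomputing its F scores. Rejecting
# requires every dataset to show an effect, so the false-positive rate is
# controlled whenever at least one dataset is null. Component-level
# correction is applied to the min-F matrix exactly as in the NBS;
# sign-consistency across all contrasts is applied as a separate, labelled
# step to define common-increase / common-decrease edge sets.

# Normalise one contrast specification into matrices + design.
as_contrast_spec <- function(x, k) {
  if (inherits(x, "list") && all(c("a", "b", "design") %in% names(x))) {
    a <- as_edge_samples(x$a)
    b <- as_edge_samples(x$b)
    design <- match.arg(x$design, c("unpaired", "paired"))
    if (design == "paired" && nrow(a) != nrow(b)) {
      stop("contrast ", k, ": paired design requires matched subjects",
           call. = FALSE)
    }
    list(a = a, b = b, design = design)
  } else {
    stop("each contrast must be a list(a=, b=, design=)", call. = FALSE)
  }
}

#' Composite minimum-F test for effects shared across datasets
#'
#' Tests, edge by edge, the composite null hypothesis that *at least one*
#' of the supplied condition contrasts has no effect. The observed edge
#' statistic is the minimum of the per-contrast F scores; each permutation
#' reshuffles exactly one contrast's data (chosen uniformly at random,
#' respecting its paired/unpaired design), recomputes that contrast's F,
#' and rebuilds the minimum -- the least favourable configuration null.
#' Supra-threshold components of the min-F matrix are corrected exactly as
#' in [nbs()]. Significant edges whose direction of effect agrees across
#' all contrasts form the common-increase / common-decrease sets.
#'
#' @param contrasts A list of contrasts (three in the primary design), each
#'   a `list(a =, b =, design =)` of subject-level edge data (see
#'   [as_edge_samples()]) and `"paired"`/`"unpaired"`.
#' @param threshold Edge threshold on the min-F statistic (default 9).
#' @param component_measure `"intensity"` or `"extent"`.
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Component significance level (default 0.05).
#' @param seed Integer seed (drives both the dataset picks and the
#'   reshuffles).
#' @return A `composite_test_result`: `min_f` matrix, per-contrast F and
#'   sign matrices, `components` and `edges` tibbles (as in [nbs()], with
#'   per-contrast signs and a `sign_consistent` flag), `common_increase`
#'   and `common_decrease` edge tibbles, and the permutation null maxima.
#' @export
composite_min_f <- function(contrasts, threshold = 9,
                            component_measure = c("intensity", "extent"),
                            n_perm = 5000, alpha = 0.05, seed = NULL) {
  component_measure <- match.arg(component_measure)
  K <- length(contrasts)
  if (K < 2) stop("need at least two contrasts", call. = FALSE)
  if (K != 3) {
    message("composite test generalised to ", K,
            " contrasts (the reference design uses 3)")
  }
  specs <- lapply(seq_len(K), function(k) as_contrast_spec(contrasts[[k]], k))
  n <- attr(specs[[1]]$a, "n_regions")
  for (s in specs) {
    if (attr(s$a, "n_regions") != n || attr(s$b, "n_regions") != n) {
      stop("contrasts measured on mismatched edge sets", call. = FALSE)
    }
  }
  ids <- attr(specs[[1]]$a, "region_ids")
  geo <- edge_geometry(n)
  ut <- upper.tri(diag(n))

  edge_f <- function(s) {
    if (s$design == "paired") f_edges_paired(unclass(s$b) - unclass(s$a))
    else f_edges_unpaired(unclass(s$a), unclass(s$b))
  }
  obs_f <- lapply(specs, edge_f)
  F_k <- do.call(cbind, lapply(obs_f, `[[`, "f"))
  S_k <- do.call(cbind, lapply(obs_f, `[[`, "sign"))
  min_f <- do.call(pmin, lapply(seq_len(K), function(k) F_k[, k]))
  obs <- supra_components(min_f, threshold, geo, n, component_measure)

  perm_f <- function(s) {
    if (s$design == "paired") {
      flip <- sample(c(-1, 1), nrow(s$a), replace = TRUE)
      f_edges_paired((unclass(s$b) - unclass(s$a)) * flip)$f
    } else {
      pool <- rbind(unclass(s$a), unclass(s$b))
      idx <- sample.int(nrow(pool))
      na <- nrow(s$a)
      f_edges_unpaired(pool[idx[seq_len(na)], , drop = FALSE],
                       pool[idx[-seq_len(na)], , drop = FALSE])$f
    }
  }
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      k <- sample.int(K, 1)
      f_new <- perm_f(specs[[k]])
      mf <- min_f
      # recompute the minimum with dataset k replaced
      others <- setdiff(seq_len(K), k)
      mf <- do.call(pmin, c(lapply(others, function(o) F_k[, o]),
                            list(f_new)))
      max_component_stat(mf, threshold, geo, n, component_measure)
    }, numeric(1))
  })

  comps <- dplyr::mutate(
    obs$components,
    p_value = vapply(.data$statistic,
                     function(s) (1 + sum(null_max >= s)) / (1 + n_perm),
                     numeric(1)))
  edges <- tibble::tibble(
    region_i = ids[geo$i[obs$edge_idx]],
    region_j = ids[geo$j[obs$edge_idx]],
    min_f = min_f[obs$edge_idx],
    component_id = obs$edge_component)
  for (k in seq_len(K)) {
    edges[[paste0("f_", k)]] <- F_k[obs$edge_idx, k]
    edges[[paste0("sign_", k)]] <- S_k[obs$edge_idx, k]
  }
  edges <- dplyr::left_join(edges, comps[, c("component_id", "p_value")],
                            by = "component_id")
  edges$significant <- edges$p_value <= alpha
  sgn_sub <- S_k[obs$edge_idx, , drop = FALSE]
  edges$sign_consistent <- rowSums(sgn_sub == 1) == K |
    rowSums(sgn_sub == -1) == K
  inc <- edges$significant & rowSums(sgn_sub == 1) == K
  dec <- edges$significant & rowSums(sgn_sub == -1) == K

  structure(
    list(min_f = edge_to_matrix(min_f, n, ids),
         f_matrices = lapply(seq_len(K), function(k)
           edge_to_matrix(F_k[, k], n, ids)),
         sign_matrices = lapply(seq_len(K), function(k)
           edge_to_matrix(S_k[, k], n, ids)),
         threshold = threshold, component_measure = component_measure,
         n_perm = n_perm, alpha = alpha, seed = seed,
         components = comps, edges = edges,
         common_increase = edges[inc, , drop = FALSE],
         common_decrease = edges[dec, , drop = FALSE],
         null_max = null_max, region_ids = ids),
    class = "composite_test_result"
  )
}

#' @export
print.composite_test_result <- function(x, ...) {
  nsig <- sum(x$components$p_value <= x$alpha)
  cat("<composite_test_result> min-F over ", length(x$f_matrices),
      " contrasts, threshold > ", x$threshold, ", ", nrow(x$components),
      " component(s), ", nsig, " significant; ",
      nrow(x$common_increase), " common-increase / ",
      nrow(x$common_decrease), " common-decrease edge(s)\n", sep = "")
  invisible(x)
}

#' Overlap of significant effects across contrasts
#'
#' Summarises which edges change consistently across contrasts: for a
#' [composite_min_f()] result, the common-increase and common-decrease edge
#' sets with the regions incident to them; for a list of per-contrast
#' [nbs()] results, the edges significant in every contrast with the same
#' direction. Also reports the signed F-sum (sum of `sign * F` over
#' significant edges) per contrast -- a scalar balance of increases versus
#' decreases.
#'
#' @param x A `composite_test_result` or a list of `nbs_result` objects
#'   over identical region sets.
#' @return A list with `common_increase` / `common_decrease` edge tibbles,
#'   `regions_increase` / `regions_decrease` character vectors (regions
#'   incident to at least one common edge), and `signed_f_sum` (named
#'   vector, one per contrast for a list input).
#' @export
overlap_summary <- function(x) {
  regions_of <- function(edges) {
    sort(unique(c(edges$region_i, edges$region_j)))
  }
  if (inherits(x, "composite_test_result")) {
    sig <- x$edges[x$edges$significant, , drop = FALSE]
    K <- length(x$f_matrices)
    sfs <- vapply(seq_len(K), function(k)
      sum(sig[[paste0("sign_", k)]] * sig[[paste0("f_", k)]]), numeric(1))
    return(list(common_increase = x$common_increase,
                common_decrease = x$common_decrease,
                regions_increase = regions_of(x$common_increase),
                regions_decrease = regions_of(x$common_decrease),
                signed_f_sum = stats::setNames(sfs, paste0("contrast_", seq_len(K)))))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "nbs_result")))
  key <- function(e) paste(e$region_i, e$region_j, sep = "~")
  sig <- lapply(x, function(r) r$edges[r$edges$significant, , drop = FALSE])
  common <- Reduce(intersect, lapply(sig, key))
  pick <- function(r, keys) r[key(r) %in% keys, , drop = FALSE]
  signs <- lapply(sig, function(e)
    stats::setNames(e$sign, key(e)))
  all_pos <- common[vapply(common, function(k)
    all(vapply(signs, function(s) s[[k]] > 0, TRUE)), TRUE)]
  all_neg <- common[vapply(common, function(k)
    all(vapply(signs, function(s) s[[k]] < 0, TRUE)), TRUE)]
  inc <- pick(sig[[1]], all_pos)
  dec <- pick(sig[[1]], all_neg)
  list(common_increase = inc, common_decrease = dec,
       regions_increase = regions_of(inc), regions_decrease = regions_of(dec),
       signed_f_sum = stats::setNames(
         vapply(x, `[[`, numeric(1), "signed_f_sum"),
         paste0("contrast_", seq_along(x))))
}
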
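# broom-style tidiers for phidnet result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an information network into an edge table
#'
#' @param x An `info_network`.
#' @param ... Unused.
#' @return A tibble with one row per unordered region pair: `region_i`,
#'   `region_j`, `measure`, `value` (nats).
#' @export
tidy.info_network <- function(x, ...) {
  n <- length(x$region_ids)
  geo <- edge_geometry(n)
  tibble::tibble(
    region_i = x$region_ids[geo$i],
    region_j = x$region_ids[geo$j],
    measure = x$measure,
    value = x$values[upper.tri(x$values)]
  )
}

#' Tidy an edgewise contrast
#'
#' @param x An `edge_contrast` from [edgewise_f()].
#' @param ... Unused.
#' @return A tibble with `region_i`, `region_j`, `f`, `sign`.
#' @export
tidy.edge_contrast <- function(x, ...) {
  n <- length(x$region_ids)
  geo <- edge_geometry(n)
  ut <- upper.tri(diag(n))
  tibble::tibble(
    region_i = x$region_ids[geo$i],
    region_j = x$region_ids[geo$j],
    f = x$f_matrix[ut],
    sign = x$sign_matrix[ut]
  )
}

#' Tidy / summarise an NBS result
#'
#' `tidy()` returns the supra-threshold edge table; `glance()` a one-row
#' summary.
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nbs_result <- function(x, ...) x$edges

#' @rdname tidy.nbs_result
#' @export
glance.nbs_result <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    component_measure = x$component_measure,
    n_perm = x$n_perm,
    alpha = x$alpha,
    n_components = nrow(x$components),
    n_significant_components = sum(x$components$p_value <= x$alpha),
    n_significant_edges = sum(x$edges$significant),
    min_p = if (nrow(x$components) > 0) min(x$components$p_value) else NA_real_,
    signed_f_sum = x$signed_f_sum
  )
}

#' Tidy / summarise a composite shared-effect test
#'
#' `tidy()` returns the supra-threshold min-F edge table (with per-contrast
#' F and sign columns); `glance()` a one-row summary.
#'
#' @param x A `composite_test_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.composite_test_result <- function(x, ...) x$edges

#' @rdname tidy.composite_test_result
#' @export
glance.composite_test_result <- function(x, ...) {
  tibble::tibble(
    n_contrasts = length(x$f_matrices),
    threshold = x$threshold,
    component_measure = x$component_measure,
    n_perm = x$n_perm,
    alpha = x$alpha,
    n_components = nrow(x$components),
    n_significant_components = sum(x$components$p_value <= x$alpha),
    n_common_increase = nrow(x$common_increase),
    n_common_decrease = nrow(x$common_decrease),
    min_p = if (nrow(x$components) > 0) min(x$components$p_value) else NA_real_
  )
}
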
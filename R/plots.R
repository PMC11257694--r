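# ggplot2 displays for networks, node profiles and statistical results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an information network
#'
#' @param object An `info_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.info_network <- function(object, ...) {
  df <- tidy.info_network(object)
  df2 <- df
  names(df2)[1:2] <- c("region_j", "region_i")
  df <- dplyr::bind_rows(df, df2)
  ggplot2::ggplot(df, ggplot2::aes(.data$region_i, .data$region_j,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = paste0(object$measure, " (nats)")) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Pairwise ", object$measure,
                                 " (tau = ", object$tau, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Rank-gradient profile plot
#'
#' Lollipop plot of the synergy-minus-redundancy rank gradient, coloured by
#' workspace membership (or role, when present).
#'
#' @param object A `node_profiles` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.node_profiles <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$gradient)
  df$region <- factor(df$region, levels = df$region)
  colour_var <- if ("role" %in% names(df)) "role" else "workspace"
  ggplot2::ggplot(df, ggplot2::aes(.data$gradient, .data$region,
                                   colour = .data[[colour_var]])) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$gradient,
                                       yend = .data$region)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "synergy rank - redundancy rank", y = NULL,
                  title = "Synergy-redundancy rank gradient") +
    ggplot2::theme_minimal()
}

#' Edge-statistic heatmap for an NBS result
#'
#' F-score heatmap with significant edges outlined.
#'
#' @param object An `nbs_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nbs_result <- function(object, ...) {
  ids <- object$contrast$region_ids
  n <- length(ids)
  geo <- edge_geometry(n)
  ut <- upper.tri(diag(n))
  df <- tibble::tibble(
    region_i = factor(ids[geo$i], levels = ids),
    region_j = factor(ids[geo$j], levels = ids),
    f = object$contrast$f_matrix[ut],
    significant = object$significant_edges[ut]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$region_i, .data$region_j)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$f)) +
    ggplot2::geom_tile(data = df[df$significant, , drop = FALSE],
                       fill = NA, colour = "red", linewidth = 0.6) +
    ggplot2::scale_fill_viridis_c(name = "F") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Edgewise F (threshold ", object$threshold,
                                 "); significant edges outlined")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
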
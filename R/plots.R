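#' Heatmap of pairwise synonymous (or nonsynonymous) distances
#'
#' @param object A `pairwise_distances` object.
#' @param which `"dS"` (default) or `"dN"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pairwise_distances
#' @export
autoplot.pairwise_distances <- function(object, which = c("dS", "dN"), ...) {
  which <- match.arg(which)
  m <- object[[which]]
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m), name1 = rownames(m)),
    -"name1", names_to = "name2", values_to = "distance"
  )
  lv <- object$names
  df$name1 <- factor(df$name1, levels = lv)
  df$name2 <- factor(df$name2, levels = rev(lv))
  ggplot2::ggplot(df, ggplot2::aes(.data$name1, .data$name2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = which) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Pairwise %s (kappa = %.3g)",
                                  which, object$kappa)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Distribution of the number of ancestral lineages
#'
#' Bar chart of g_nk(t) over k, annotated with the upper-tail
#' probabilities.
#'
#' @param object A `lineage_distribution` tibble from
#'   [lineage_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lineage_distribution
#' @export
autoplot.lineage_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "ancestral lineages k",
      y = expression(g[nk](t)),
      title = sprintf("Ancestral lineage distribution, n = %d, t = %.3g",
                      object$n[[1L]], object$t[[1L]])
    ) +
    ggplot2::theme_minimal()
}

#' Per-branch parsimony change counts
#'
#' Bar chart of the number of substitutions assigned to each branch,
#' labelled by the branch's child node (tip name for terminal branches).
#'
#' @param object A `branch_change_map` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot branch_change_map
#' @export
autoplot.branch_change_map <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$n_changes > 0, , drop = FALSE]
  df$child_label <- factor(df$child_label,
                           levels = df$child_label[order(df$n_changes)])
  ggplot2::ggplot(df, ggplot2::aes(.data$n_changes, .data$child_label)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "mapped substitutions", y = "branch (child node)",
                  title = "Parsimony-mapped substitutions per branch") +
    ggplot2::theme_minimal()
}
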
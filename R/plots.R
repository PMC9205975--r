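#' Plot expression time courses
#'
#' Line plot of each gene's expression over time, optionally restricted to a
#' subset of genes and z-scored for pattern comparison.
#'
#' @param df Expression table (gene column first).
#' @param genes Optional character vector of genes to show.
#' @param scale If `TRUE`, z-score each profile before plotting.
#' @return A ggplot object.
#' @export
plot_expression_profiles <- function(df, genes = NULL, scale = FALSE) {
  validate_expression(df)
  names(df)[1L] <- "gene"
  if (!is.null(genes)) df <- dplyr::filter(df, .data$gene %in% genes)
  long <- df |>
    tidyr::pivot_longer(-"gene", names_to = "timepoint",
                        values_to = "expression") |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(time_index = dplyr::row_number()) |>
    dplyr::ungroup()
  if (scale) {
    long <- long |>
      dplyr::group_by(.data$gene) |>
      dplyr::mutate(expression =
                      (.data$expression - mean(.data$expression)) /
                      sd(.data$expression)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$time_index, .data$expression,
                                     color = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time point", y = if (scale) "z-scored expression"
                  else "Expression") +
    ggplot2::theme_minimal()
}

#' @describeIn benchmark_network ROC and precision-recall curves of a
#'   benchmark, drawn side by side with their areas in the panel labels.
#' @param object A `grn_benchmark`.
#' @export
autoplot.grn_benchmark <- function(object, ...) {
  curve <- object$curve
  roc <- tibble(x = c(0, curve$fpr), y = c(0, curve$tpr),
                panel = sprintf("ROC (AUROC = %.3f)", object$auroc))
  pr <- tibble(x = c(0, curve$recall),
               y = c(curve$precision[1L], curve$precision),
               panel = sprintf("PR (AUPRC = %.3f)", object$auprc))
  ggplot2::ggplot(dplyr::bind_rows(roc, pr),
                  ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "FPR / Recall", y = "TPR / Precision") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @describeIn fuzzy_cmeans_cluster Cluster-mean expression patterns: the
#'   average z-scored profile of each cluster over time.
#' @param object A `cluster_assignment`.
#' @param df The expression table that was clustered.
#' @param ... Unused.
#' @export
autoplot.cluster_assignment <- function(object, df, ...) {
  m <- zscore_profiles(expr_matrix(df))
  long <- tibble(
    gene = rep(rownames(m), ncol(m)),
    time_index = rep(seq_len(ncol(m)), each = nrow(m)),
    expression = as.vector(m)
  ) |>
    dplyr::inner_join(tibble(gene = object$gene, cluster = object$cluster),
                      by = "gene") |>
    dplyr::group_by(.data$cluster, .data$time_index) |>
    dplyr::summarise(expression = mean(.data$expression), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_index, .data$expression)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "Time point", y = "Mean z-scored expression") +
    ggplot2::theme_minimal()
}

#' Plot a directed regulatory network
#'
#' Draws a screened edge list as a directed graph (Fruchterman-Reingold
#' layout), with edge darkness proportional to transfer entropy.
#'
#' @param edges Edge tibble (`source`, `target`, `te`).
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(edges, seed = 1) {
  g <- build_network(edges)
  coords <- with_local_seed(seed, function() {
    igraph::layout_with_fr(g)
  })
  nodes <- tibble(name = igraph::V(g)$name,
                  x = coords[, 1L], y = coords[, 2L])
  seg <- edges |>
    dplyr::left_join(nodes, by = c(source = "name")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c(target = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, alpha = .data$te),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(alpha = "TE (bits)")
}
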
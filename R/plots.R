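#' Plot the consensus similarity matrix ordered by cluster
#'
#' Heatmap of the pairwise consensus similarity with genes ordered by their
#' final cluster, so recovered modules appear as blocks on the diagonal.
#'
#' @param object A `consensus_clust` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_clust <- function(object, ...) {
  ord <- order(object$assignment$cluster, object$assignment$gene_id,
               na.last = TRUE)
  genes <- object$assignment$gene_id[ord]
  sim <- object$consensus$similarity[genes, genes]
  df <- tibble::tibble(
    gene_a = factor(rep(genes, times = length(genes)), levels = genes),
    gene_b = factor(rep(genes, each = length(genes)), levels = genes),
    similarity = as.vector(sim))
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_a, .data$gene_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "consensus\nsimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot per-cluster fold-change profiles
#'
#' Line plot of each gene's log2 fold-change profile across conditions,
#' faceted by cluster, with the cluster mean overlaid — the usual way to
#' inspect response clusters (e.g. transient up-then-down behaviour).
#'
#' @param fc Fold-change tibble (`gene_id` + condition columns).
#' @param clusters Cluster assignment tibble (`gene_id`, `cluster`).
#' @return A ggplot object.
#' @export
plot_cluster_profiles <- function(fc, clusters) {
  check_gene_table(fc, "fold-change matrix")
  conds <- setdiff(names(fc), "gene_id")
  long <- tidyr::pivot_longer(
    dplyr::inner_join(fc, clusters[c("gene_id", "cluster")], by = "gene_id"),
    dplyr::all_of(conds), names_to = "condition", values_to = "log2fc")
  long$condition <- factor(long$condition, levels = conds)
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$cluster, .data$condition),
    log2fc = mean(.data$log2fc), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$log2fc)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene_id),
                       alpha = 0.15, colour = "grey40") +
    ggplot2::geom_line(data = means, ggplot2::aes(group = 1),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "log2 fold change") +
    ggplot2::theme_bw()
}

#' Bar chart of cluster expression relative to a reference population
#'
#' @param summary Output of [summarize_cluster_expression()].
#' @return A ggplot object (one bar group per cluster, one bar per
#'   population; the reference population sits at 1).
#' @export
plot_cluster_expression <- function(summary) {
  pops <- setdiff(names(summary), "cluster")
  long <- tidyr::pivot_longer(summary, dplyr::all_of(pops),
                              names_to = "population",
                              values_to = "relative_expression")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$cluster),
                                     .data$relative_expression,
                                     fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "cluster", y = "expression relative to reference") +
    ggplot2::theme_bw()
}

#' Dot plot of term-enrichment results
#'
#' @param enrichment Output of [term_enrichment()] (optionally with a
#'   `cluster` column, which is faceted).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  if (!nrow(enrichment)) rlang::abort("no enriched terms to plot")
  p <- ggplot2::ggplot(enrichment,
                       ggplot2::aes(-log10(.data$p_value),
                                    stats::reorder(.data$term, -.data$p_value),
                                    size = .data$n_overrep)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "-log10 p", y = NULL, size = "genes") +
    ggplot2::theme_bw()
  if ("cluster" %in% names(enrichment)) {
    p <- p + ggplot2::facet_wrap(~cluster, scales = "free_y")
  }
  p
}
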
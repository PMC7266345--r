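#' Tidy a consensus clustering result
#'
#' @param x A `consensus_clust` object.
#' @param ... Unused.
#' @return The cluster assignment as a tibble (`gene_id`, `cluster`;
#'   `cluster` is `NA` for unclustered genes).
#' @export
tidy.consensus_clust <- function(x, ...) {
  x$assignment
}

#' One-row summary of a consensus clustering result
#'
#' @param x A `consensus_clust` object.
#' @param ... Unused.
#' @return A one-row tibble: gene counts, number of clusters, number of
#'   unclustered genes, map-equation codelength of the returned partition
#'   (bits), and the main parameters.
#' @export
glance.consensus_clust <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$assignment),
    n_clusters = length(unique(stats::na.omit(x$assignment$cluster))),
    n_unclustered = sum(is.na(x$assignment$cluster)),
    codelength = map_codelength(x$graph, x$assignment),
    n_iterations = x$params$config$n_iterations,
    retain_frac = x$params$retain_frac,
    n_trials = x$params$n_trials)
}

#' Tidy a consensus matrix into pairwise records
#'
#' @param x A `consensus_matrix` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered gene pair that was sampled
#'   together at least once: `gene_a`, `gene_b`, `co_cluster`, `co_sample`,
#'   `similarity`.
#' @export
tidy.consensus_matrix <- function(x, ...) {
  ut <- upper.tri(x$co_sample)
  idx <- which(ut & x$co_sample > 0, arr.ind = TRUE)
  tibble::tibble(gene_a = x$gene_id[idx[, 1]],
                 gene_b = x$gene_id[idx[, 2]],
                 co_cluster = x$co_cluster[idx],
                 co_sample = x$co_sample[idx],
                 similarity = x$similarity[idx])
}
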
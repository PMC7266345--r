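#' Consensus-cluster a fold-change matrix
#'
#' The full clustering procedure for regulator-response profiles: quantile
#' normalization of the log2 fold changes, a resampled k-means consensus
#' ensemble, personalized-PageRank sparsification of the consensus
#' similarity, and Infomap partitioning of the resulting weighted graph.
#'
#' @param fc Fold-change tibble (`gene_id` + condition columns). Normalized
#'   automatically unless already flagged (or `normalize = FALSE`).
#' @param cfg An [ensemble_config()]; its `seed` also seeds the Infomap
#'   stage (via a fixed derivation).
#' @param retain_frac Neighbour fraction for [pagerank_filter()].
#' @param n_trials Infomap trials for [infomap_cluster()].
#' @param damping PageRank damping factor.
#' @param normalize Quantile-normalize first (default `TRUE`; skipped when
#'   the input is already flagged normalized).
#' @param keep_log Store the per-iteration ensemble log (see
#'   [kmeans_ensemble()]).
#' @return A `consensus_clust` object: `assignment` (tibble `gene_id`,
#'   `cluster`), `consensus` (the `consensus_matrix`), `graph` (the filtered
#'   `consensus_graph`), `params`, and per-stage `timings` (seconds).
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' sim <- generate_foldchange_matrix(
#'   list(up = c(a = 2, b = 2), down = c(a = -2, b = -2)),
#'   genes_per_cluster = 8, noise = noise_model(fc_noise_sd = 0.1, seed = 2))
#' res <- consensus_cluster(sim$fc, ensemble_config(n_iterations = 30, seed = 2),
#'                          n_trials = 20)
#' glance(res)
#' @export
consensus_cluster <- function(fc, cfg = ensemble_config(), retain_frac = 0.65,
                              n_trials = 1000L, damping = 0.85,
                              normalize = TRUE, keep_log = FALSE) {
  timings <- c()
  tic <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, secs = proc.time()[["elapsed"]] - t0)
  }

  if (normalize && !isTRUE(attr(fc, "normalized"))) {
    st <- tic(quantile_normalize(fc))
    fc <- st$val; timings["normalize"] <- st$secs
  } else if (is.null(attr(fc, "normalized"))) {
    # deliberate choice to cluster raw log2 fold changes
    attr(fc, "normalized") <- FALSE
  }
  st <- tic(kmeans_ensemble(fc, cfg, keep_log = keep_log))
  cm <- st$val; timings["ensemble"] <- st$secs
  st <- tic(pagerank_filter(cm, retain_frac = retain_frac, damping = damping))
  graph <- st$val; timings["pagerank_filter"] <- st$secs
  st <- tic(infomap_cluster(graph, n_trials = n_trials,
                            seed = derive_seed(cfg$seed, 0L)))
  assign_canonical <- st$val; timings["infomap"] <- st$secs

  assignment <- assign_canonical[match(fc$gene_id, assign_canonical$gene_id), ]
  structure(list(assignment = assignment,
                 consensus = cm,
                 graph = graph,
                 params = list(config = cfg, retain_frac = retain_frac,
                               n_trials = as.integer(n_trials),
                               damping = damping),
                 timings = timings),
            class = "consensus_clust")
}

#' @export
print.consensus_clust <- function(x, ...) {
  k <- length(unique(stats::na.omit(x$assignment$cluster)))
  cat("Consensus clustering of", nrow(x$assignment), "genes:",
      k, "clusters,", sum(is.na(x$assignment$cluster)), "unclustered\n")
  cat("  iterations:", x$params$config$n_iterations,
      " retain_frac:", x$params$retain_frac,
      " infomap trials:", x$params$n_trials, "\n")
  invisible(x)
}

#' Hierarchical clustering of a fold-change matrix
#'
#' Agglomerative clustering of gene response profiles (Euclidean distance,
#' average linkage by default), cut to exactly `n_clusters` — the procedure
#' used for time-course matrices where a fixed, manually chosen number of
#' clusters is wanted. Deterministic.
#'
#' @param fc Fold-change tibble (`gene_id` + numeric condition columns),
#'   finite entries.
#' @param n_clusters Number of clusters (<= number of genes).
#' @param method Linkage passed to [stats::hclust()] (default "average").
#' @return A cluster-assignment tibble (`gene_id`, `cluster`), labels
#'   renumbered contiguously in order of first appearance.
#' @export
hierarchical_cluster <- function(fc, n_clusters, method = "average") {
  check_gene_table(fc, "fold-change matrix")
  m <- gene_matrix(fc)
  if (!all(is.finite(m))) abort_data("fold-change matrix must be finite")
  if (n_clusters > nrow(m)) {
    abort_data("n_clusters exceeds the number of genes")
  }
  cl <- cutree(hclust(dist(m), method = method), k = n_clusters)
  tibble::tibble(gene_id = rownames(m),
                 cluster = as.integer(match(cl, unique(cl))))
}
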
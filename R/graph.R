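#' Sparsify a consensus matrix with personalized PageRank
#'
#' Prunes weak consensus links: each gene in turn is made the sole restart
#' node of a personalized PageRank walk on the similarity-weighted consensus
#' graph, its neighbours are ranked by their PageRank score, and only the
#' top `ceiling(retain_frac * degree)` neighbours keep their edge from that
#' gene (ties broken by gene id). The retained directed selections are then
#' symmetrized by union — an edge survives if either endpoint retained it —
#' and keep their consensus-similarity weights. With `retain_frac = 1` the
#' graph equals the thresholded consensus matrix.
#'
#' @param cm A `consensus_matrix` (see [kmeans_ensemble()]) or a symmetric
#'   similarity matrix with gene ids as dimnames.
#' @param retain_frac Fraction of each gene's neighbours to retain (default
#'   0.65, the published choice).
#' @param damping PageRank damping factor (default 0.85).
#' @param min_similarity Optional node filter: genes whose strongest
#'   similarity is below this are dropped before ranking (default 0, off).
#' @return A `consensus_graph` object: list with the undirected weighted
#'   `graph` (igraph; isolated genes kept as isolated vertices), `gene_id`,
#'   `retain_frac` and `damping`.
#' @export
pagerank_filter <- function(cm, retain_frac = 0.65, damping = 0.85,
                            min_similarity = 0) {
  sim <- if (inherits(cm, "consensus_matrix")) cm$similarity else as.matrix(cm)
  if (is.null(rownames(sim))) {
    dimnames(sim) <- list(paste0("g", seq_len(nrow(sim))),
                          paste0("g", seq_len(nrow(sim))))
  }
  if (!isTRUE(all.equal(sim, t(sim)))) abort_data("similarity must be symmetric")
  stopifnot(retain_frac > 0, retain_frac <= 1, damping > 0, damping < 1)
  gene_id <- rownames(sim)
  ord <- order(gene_id)
  sim <- sim[ord, ord, drop = FALSE]
  diag(sim) <- 0

  if (min_similarity > 0) {
    strongest <- apply(sim, 1, max)
    weak <- rownames(sim)[strongest < min_similarity]
    if (length(weak)) sim[weak, ] <- sim[, weak] <- 0
  }

  g_full <- igraph::graph_from_adjacency_matrix(sim, mode = "undirected",
                                                weighted = TRUE)
  n <- nrow(sim)
  deg <- igraph::degree(g_full)
  if (any(deg == 0)) {
    message(sum(deg == 0), " isolated gene(s) kept as isolated nodes")
  }

  keep <- matrix(FALSE, n, n, dimnames = dimnames(sim))
  for (v in seq_len(n)) {
    nb <- which(sim[v, ] > 0)
    if (!length(nb)) next
    reset <- numeric(n); reset[v] <- 1
    pr <- igraph::page_rank(g_full, damping = damping,
                            personalized = reset)$vector
    ranked <- nb[order(-pr[nb], rownames(sim)[nb])]
    top <- ranked[seq_len(ceiling(retain_frac * length(nb)))]
    keep[v, top] <- TRUE
  }
  keep <- keep | t(keep)
  adj <- sim * keep
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  structure(list(graph = g, gene_id = rownames(sim),
                 retain_frac = retain_frac, damping = damping),
            class = "consensus_graph")
}

#' Partition a consensus graph with Infomap
#'
#' Runs the Infomap map-equation community-detection algorithm on the
#' filtered consensus graph, keeping the best of `n_trials` randomized
#' trials (the published setting is 1000 trials). Isolated genes are
#' labelled unclustered (`NA`); cluster labels are renumbered contiguously
#' from 1 in order of first appearance along the canonical gene order.
#'
#' @param g A `consensus_graph` (see [pagerank_filter()]) or an undirected
#'   weighted igraph object with vertex names.
#' @param n_trials Number of Infomap trials (default 1000).
#' @param seed Integer seed making the randomized trials reproducible.
#' @return A cluster-assignment tibble (`gene_id`, `cluster`) where
#'   `cluster` is integer or `NA` for unclustered genes.
#' @export
infomap_cluster <- function(g, n_trials = 1000L, seed = 1L) {
  graph <- if (inherits(g, "consensus_graph")) g$graph else g
  if (igraph::vcount(graph) == 0) {
    return(tibble::tibble(gene_id = character(), cluster = integer()))
  }
  gene_id <- igraph::V(graph)$name
  isolated <- igraph::degree(graph) == 0
  memb <- rep(NA_integer_, length(gene_id))
  if (any(!isolated)) {
    sub <- igraph::induced_subgraph(graph, which(!isolated))
    comm <- with_seed(as.integer(seed), {
      igraph::cluster_infomap(sub, e.weights = igraph::E(sub)$weight,
                              nb.trials = as.integer(n_trials))
    })
    memb[!isolated] <- igraph::membership(comm)
  }
  ord <- order(gene_id)
  relabel <- match(memb, unique(memb[ord][!is.na(memb[ord])]))
  tibble::tibble(gene_id = gene_id, cluster = as.integer(relabel))
}

#' Map-equation description length of a partition
#'
#' Computes the two-level map-equation codelength (in bits) of an arbitrary
#' partition of an undirected weighted graph, using the stationary visit
#' rates of the unrecorded random walk (node strength over twice the total
#' edge weight). Useful for comparing a returned partition against, e.g.,
#' the trivial one-module partition.
#'
#' @param graph Undirected weighted igraph (or `consensus_graph`).
#' @param membership Integer vector (or `gene_id`/`cluster` tibble) giving
#'   each vertex's module; `NA` vertices are ignored.
#' @return Codelength in bits.
#' @export
map_codelength <- function(graph, membership) {
  if (inherits(graph, "consensus_graph")) graph <- graph$graph
  if (is.data.frame(membership)) {
    membership <- membership$cluster[match(igraph::V(graph)$name,
                                           membership$gene_id)]
  }
  keep <- !is.na(membership)
  g <- igraph::induced_subgraph(graph, which(keep))
  membership <- membership[keep]
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  tw <- sum(w)
  if (tw == 0) return(0)
  p <- igraph::strength(g, weights = w) / (2 * tw)

  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  inter <- membership[ends[, 1]] != membership[ends[, 2]]
  mods <- sort(unique(membership))
  # exit rate of each module: weight crossing its boundary over 2W
  q <- vapply(mods, function(m) {
    sum(w[inter & (membership[ends[, 1]] == m | membership[ends[, 2]] == m)])
  }, numeric(1))
  q <- q / (2 * tw)
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  Q <- sum(q)
  index_term <- if (Q > 0) Q * (-sum(plogp(q / Q))) else 0
  module_term <- sum(vapply(seq_along(mods), function(i) {
    pm <- p[membership == mods[i]]
    tot <- q[i] + sum(pm)
    if (tot == 0) return(0)
    tot * (-sum(plogp(c(q[i], pm) / tot)))
  }, numeric(1)))
  index_term + module_term
}
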
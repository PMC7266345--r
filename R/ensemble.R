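#' Configure the resampled k-means ensemble
#'
#' Holds the ensemble parameters of the consensus-clustering procedure: in
#' each iteration the number of clusters k is drawn uniformly from
#' `k_min .. floor(sqrt(n))` (n = total gene count) and a gene subsample of
#' at least `subsample_min_frac * n` genes (without replacement) is
#' clustered by k-means. Defaults follow the published procedure: 4000
#' iterations, 3 <= k <= sqrt(n), an 80% subsampling floor, and k-means
#' with 500 maximum iterations and 20 random restarts.
#'
#' @param n_iterations Number of ensemble iterations (>= 1).
#' @param k_min Smallest k sampled (>= 2; default 3).
#' @param subsample_min_frac Lower bound on the subsample fraction, in
#'   (0, 1]; the subsample size is drawn uniformly between this floor and n.
#' @param kmeans_max_iter,kmeans_restarts `iter.max` and `nstart` passed to
#'   [stats::kmeans()].
#' @param seed Master seed; per-iteration streams are derived from it with
#'   [derive_seed()] so results do not depend on execution order.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(n_iterations = 4000L, k_min = 3L,
                            subsample_min_frac = 0.8,
                            kmeans_max_iter = 500L, kmeans_restarts = 20L,
                            seed = 1L) {
  stopifnot(n_iterations >= 1, k_min >= 2,
            subsample_min_frac > 0, subsample_min_frac <= 1,
            kmeans_max_iter >= 1, kmeans_restarts >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 k_min = as.integer(k_min),
                 subsample_min_frac = subsample_min_frac,
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

# k-means on possibly-duplicated rows: cluster the unique rows and map the
# assignment back, so identical profiles always co-cluster and k never
# exceeds the number of distinct points (k is capped there).
kmeans_assign <- function(m, k, iter.max, nstart) {
  key <- apply(m, 1, paste, collapse = "\r")
  uniq <- !duplicated(key)
  mu <- m[uniq, , drop = FALSE]
  k_eff <- min(k, nrow(mu))
  if (k_eff >= nrow(mu)) {
    ua <- seq_len(nrow(mu))
  } else {
    ua <- kmeans(mu, centers = k_eff, iter.max = iter.max, nstart = nstart)$cluster
  }
  unname(ua[match(key, key[uniq])])
}

#' Run the resampled k-means consensus ensemble
#'
#' Repeatedly subsamples the genes, clusters the subsample with k-means at a
#' randomly drawn k, and accumulates, for every gene pair, how often the two
#' genes were sampled together (`co_sample`) and how often they landed in
#' the same cluster (`co_cluster`). The consensus similarity is the
#' elementwise quotient of the two counts. Fully reproducible from
#' `cfg$seed`; gene order in the input does not affect the result (genes are
#' processed in canonical id order internally).
#'
#' @param fc A quantile-normalized fold-change tibble (`gene_id` + condition
#'   columns); a warning is issued if the `normalized` flag is missing.
#' @param cfg An [ensemble_config()].
#' @param keep_log If `TRUE`, store each iteration's sampled gene ids and
#'   cluster assignment (used for oracle verification; memory-heavy for
#'   large runs).
#' @return A `consensus_matrix` object: list with `gene_id`, integer
#'   matrices `co_cluster` and `co_sample`, the `similarity` matrix in
#'   `[0, 1]`, the `config`, and (optionally) the iteration `log`.
#' @export
kmeans_ensemble <- function(fc, cfg = ensemble_config(), keep_log = FALSE) {
  check_gene_table(fc, "fold-change matrix")
  if (is.null(attr(fc, "normalized"))) {
    warning("input fold-change matrix is not flagged as quantile-normalized")
  }
  m_in <- gene_matrix(fc)
  if (anyNA(m_in)) abort_data("fold-change matrix contains NA; fill first")
  ord <- order(rownames(m_in))
  m <- m_in[ord, , drop = FALSE]
  n <- nrow(m)
  k_max <- floor(sqrt(n))
  if (k_max < cfg$k_min) {
    abort_data(sprintf("empty k range: need n >= k_min^2 (n = %d, k_min = %d)",
                       n, cfg$k_min))
  }
  size_min <- ceiling(cfg$subsample_min_frac * n)

  cc <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  cs <- cc
  log <- if (keep_log) vector("list", cfg$n_iterations)

  for (i in seq_len(cfg$n_iterations)) {
    it <- with_seed(derive_seed(cfg$seed, i), {
      repeat {
        k <- sample(seq.int(cfg$k_min, k_max), 1L)
        size <- sample(seq.int(size_min, n), 1L)
        if (size >= k) break
        message("iteration ", i, ": subsample smaller than k, redrawn")
      }
      idx <- sort(sample.int(n, size))
      assign <- kmeans_assign(m[idx, , drop = FALSE], k,
                              cfg$kmeans_max_iter, cfg$kmeans_restarts)
      list(k = k, idx = idx, assign = assign)
    })
    cs[it$idx, it$idx] <- cs[it$idx, it$idx] + 1L
    for (cl in unique(it$assign)) {
      mem <- it$idx[it$assign == cl]
      cc[mem, mem] <- cc[mem, mem] + 1L
    }
    if (keep_log) {
      log[[i]] <- list(k = it$k, sampled = rownames(m)[it$idx],
                       assignment = setNames(it$assign, rownames(m)[it$idx]))
    }
  }

  back <- match(rownames(m_in), rownames(m))
  structure(list(gene_id = rownames(m_in),
                 co_cluster = cc[back, back, drop = FALSE],
                 co_sample = cs[back, back, drop = FALSE],
                 similarity = consensus_similarity(cc, cs)[back, back, drop = FALSE],
                 config = cfg,
                 log = log),
            class = "consensus_matrix")
}

#' Consensus similarity from co-clustering counts
#'
#' The pairwise consensus similarity is the number of times two genes
#' appeared in the same cluster divided by the number of times they were
#' sampled together; pairs never sampled together get similarity 0 by
#' convention.
#'
#' @param co_cluster,co_sample Symmetric nonnegative integer matrices with
#'   `co_cluster <= co_sample` elementwise.
#' @return Symmetric similarity matrix with entries in `[0, 1]`.
#' @examples
#' consensus_similarity(matrix(4), matrix(10))
#' @export
consensus_similarity <- function(co_cluster, co_sample) {
  co_cluster <- as.matrix(co_cluster)
  co_sample <- as.matrix(co_sample)
  if (!identical(dim(co_cluster), dim(co_sample))) {
    abort_data("count matrices must have identical dimensions")
  }
  if (any(co_cluster > co_sample)) {
    abort_data("corrupt ensemble: co_cluster exceeds co_sample")
  }
  if (any(co_cluster < 0) || any(co_sample < 0)) {
    abort_data("counts must be nonnegative")
  }
  sim <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  dimnames(sim) <- dimnames(co_sample)
  sim
}
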
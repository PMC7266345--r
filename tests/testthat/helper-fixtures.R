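# Shared fixtures and independent oracles, all built in code.

# Six-gene contrast-table fixture for the enrichment-calling rule, one
# epidermal group (REV, KAN1, BFP). Hand evaluation at lfc_min = 1 (strict),
# padj_max = 0.05:
#   gA: one-contrast hit (REV vs KAN1 1.5 / 0.01)            -> REV
#   gB: both REV contrasts hit (2 / 0.001)                   -> REV
#   gC: fold change only (2 / 0.20)                          -> none
#   gD: p-value only (0.5 / 0.001)                           -> none
#   gE: boundary log2fc = 1.0 exactly, rule is strict ">"    -> none
#   gF: all null                                             -> none
deg_fixture <- function() {
  rows <- list(
    c("gA", "REV_vs_KAN1", 1.5, 0.01), c("gA", "REV_vs_BFP", 0.2, 0.90),
    c("gA", "KAN1_vs_BFP", 0.0, 1.00),
    c("gB", "REV_vs_KAN1", 2.0, 0.001), c("gB", "REV_vs_BFP", 2.0, 0.001),
    c("gB", "KAN1_vs_BFP", 0.0, 1.00),
    c("gC", "REV_vs_KAN1", 2.0, 0.20), c("gC", "REV_vs_BFP", 0.1, 0.80),
    c("gC", "KAN1_vs_BFP", 0.0, 1.00),
    c("gD", "REV_vs_KAN1", 0.5, 0.001), c("gD", "REV_vs_BFP", 0.3, 0.40),
    c("gD", "KAN1_vs_BFP", 0.0, 1.00),
    c("gE", "REV_vs_KAN1", 1.0, 0.01), c("gE", "REV_vs_BFP", 1.0, 0.01),
    c("gE", "KAN1_vs_BFP", 0.0, 1.00),
    c("gF", "REV_vs_KAN1", 0.0, 1.00), c("gF", "REV_vs_BFP", 0.0, 1.00),
    c("gF", "KAN1_vs_BFP", 0.0, 1.00))
  tibble::tibble(
    gene_id = vapply(rows, `[`, "", 1),
    contrast = vapply(rows, `[`, "", 2),
    log2fc = as.numeric(vapply(rows, `[`, "", 3)),
    padj = as.numeric(vapply(rows, `[`, "", 4)))
}

deg_fixture_expected <- list(
  enriched = list(REV = c("gA", "gB"), KAN1 = character(), BFP = character()),
  sectors = tibble::tibble(gene_id = c("gA", "gB"),
                           sector = c("REV-only", "REV-only")))

# star-graph similarity: hub connected to `n_leaves` leaves, equal weight
star_similarity <- function(n_leaves = 10, w = 0.8) {
  ids <- c("hub", sprintf("leaf%02d", seq_len(n_leaves)))
  s <- matrix(0, n_leaves + 1, n_leaves + 1, dimnames = list(ids, ids))
  s["hub", -1] <- w
  s[-1, "hub"] <- w
  diag(s) <- 1
  s
}

# two planted blocks with given within/between similarity
block_similarity <- function(n_per = 20, within = 0.9, between = 0.05) {
  n <- 2 * n_per
  ids <- sprintf("g%03d", seq_len(n))
  s <- matrix(between, n, n, dimnames = list(ids, ids))
  s[seq_len(n_per), seq_len(n_per)] <- within
  s[n_per + seq_len(n_per), n_per + seq_len(n_per)] <- within
  diag(s) <- 1
  s
}

# exact hypergeometric upper-tail oracle by explicit combinatorial sum;
# all choose() values are integers < 2^53 for universe <= 30, so the
# arithmetic is exact
hyper_tail_oracle <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  j <- seq.int(max(k, max(0, n - (N - K))), min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# independent double-loop recount of the consensus similarity from the
# stored per-iteration partitions
brute_similarity <- function(ensemble) {
  ids <- ensemble$gene_id
  n <- length(ids)
  cc <- matrix(0, n, n, dimnames = list(ids, ids))
  cs <- cc
  for (it in ensemble$log) {
    sampled <- it$sampled
    for (a in seq_along(sampled)) {
      for (b in seq_along(sampled)) {
        ga <- sampled[a]; gb <- sampled[b]
        cs[ga, gb] <- cs[ga, gb] + 1
        if (it$assignment[[ga]] == it$assignment[[gb]]) {
          cc[ga, gb] <- cc[ga, gb] + 1
        }
      }
    }
  }
  ifelse(cs > 0, cc / cs, 0)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

transient_profiles <- function() {
  list(transient = c(h6 = 1.7, h16 = -1.4),
       co_up = c(h6 = 1.7, h16 = 1.7),
       co_down = c(h6 = -1.5, h16 = -1.5))
}

five_cluster_profiles <- function() {
  list(rev_up = c(REV_6h = 2, REV_16h = 2, KAN1_6h = 0, KAN1_16h = 0),
       rev_down = c(REV_6h = -2, REV_16h = -2, KAN1_6h = 0, KAN1_16h = 0),
       rev_transient = c(REV_6h = 1.7, REV_16h = -1.4, KAN1_6h = 0, KAN1_16h = 0),
       kan1_up = c(REV_6h = 0, REV_16h = 0, KAN1_6h = 2, KAN1_16h = 2),
       kan1_down = c(REV_6h = 0, REV_16h = 0, KAN1_6h = -2, KAN1_16h = -2))
}
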
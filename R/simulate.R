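#' Simulate cell-type count matrices with planted enrichment
#'
#' Draws a genes x samples table of negative-binomial counts emulating a
#' FACS-sorted bulk RNA-seq experiment. A fraction of genes is planted as
#' enriched in one population, or in a pair of populations of the same
#' tissue-layer group: their expected counts are shifted by `effect_size`
#' (log2 units) in the labelled population(s) relative to the other
#' populations of the same group. The planted truth is returned alongside so
#' recovery of the enriched sets can be scored.
#'
#' @param design A [population_design()].
#' @param n_genes Number of genes (>= 10).
#' @param frac_enriched Fraction of genes planted as enriched, in `[0, 1]`.
#' @param effect_size Log2-scale mean shift for planted genes.
#' @param noise A [noise_model()]; its `seed` makes the draw reproducible.
#' @return A list of class `celltype_sim`: `counts` (tibble, `gene_id` +
#'   one column per sample named `<population>.r<i>`), `truth` (tibble
#'   `gene_id`, `label` — a population, `"popA+popB"`, or `NA` —, and
#'   `effect_size`), `samples` (sample -> population map) and `design`.
#' @examples
#' sim <- generate_celltype_counts(population_design(), n_genes = 50,
#'                                 frac_enriched = 0.2, effect_size = 2,
#'                                 noise = noise_model(seed = 7))
#' dim(sim$counts)
#' @export
generate_celltype_counts <- function(design, n_genes, frac_enriched = 0.2,
                                     effect_size = 2, noise = noise_model()) {
  design <- as_population_design(design)
  stopifnot(n_genes >= 10, frac_enriched >= 0, frac_enriched <= 1)
  samples <- design_samples(design)

  # candidate enrichment labels: each population, and each within-group pair
  singles <- design$population
  pairs <- unlist(lapply(split(design$population, design$group), function(p) {
    if (length(p) < 2) return(character())
    cmb <- utils::combn(sort(p), 2)
    apply(cmb, 2, paste, collapse = "+")
  }), use.names = FALSE)
  labels_pool <- c(singles, pairs)

  gene_id <- sprintf("g%05d", seq_len(n_genes))
  n_planted <- round(frac_enriched * n_genes)

  with_seed(noise$seed, {
    baseline <- rlnorm(n_genes, noise$baseline_meanlog, noise$baseline_sdlog)
    planted_idx <- sort(sample.int(n_genes, n_planted))
    label <- rep(NA_character_, n_genes)
    if (n_planted > 0) {
      label[planted_idx] <- sample(labels_pool, n_planted, replace = TRUE)
    }

    mu <- matrix(baseline, n_genes, nrow(samples),
                 dimnames = list(gene_id, samples$sample))
    for (i in planted_idx) {
      pops <- strsplit(label[i], "+", fixed = TRUE)[[1]]
      mu[i, samples$population %in% pops] <-
        mu[i, samples$population %in% pops] * 2^effect_size
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / noise$dispersion),
                     n_genes, ncol(mu), dimnames = dimnames(mu))
  })

  structure(list(
    counts = matrix_to_tibble(counts),
    truth = tibble::tibble(gene_id = gene_id, label = label,
                           effect_size = ifelse(is.na(label), 0, effect_size)),
    samples = samples,
    design = design
  ), class = "celltype_sim")
}

#' Simulate a fold-change matrix with planted response clusters
#'
#' Builds a genes x conditions matrix of log2 fold changes where each gene's
#' row is its cluster's mean profile plus i.i.d. Gaussian noise. Profiles
#' mimic condition-by-time regulator responses (e.g. REV/KAN1 induction at
#' 6 h and 16 h); include a profile that is positive early and negative late
#' to emulate a transient response cluster.
#'
#' @param cluster_profiles Named list of equal-length named numeric vectors
#'   (condition -> mean log2 fold change); at least 2 profiles covering the
#'   same conditions.
#' @param genes_per_cluster Integer, recycled across profiles.
#' @param noise A [noise_model()]; `fc_noise_sd` and `seed` are used.
#' @return A list of class `fc_sim` with `fc` (tibble, `gene_id` + one
#'   numeric column per condition) and `truth` (tibble `gene_id`, `cluster`).
#' @examples
#' profs <- list(up = c(h6 = 2, h16 = 2), transient = c(h6 = 1.7, h16 = -1.4))
#' sim <- generate_foldchange_matrix(profs, genes_per_cluster = 20,
#'                                   noise = noise_model(fc_noise_sd = 0.3, seed = 1))
#' head(sim$fc)
#' @export
generate_foldchange_matrix <- function(cluster_profiles, genes_per_cluster,
                                       noise = noise_model()) {
  if (length(cluster_profiles) < 2) abort_data("need >= 2 cluster profiles")
  conds <- names(cluster_profiles[[1]])
  if (is.null(conds) || any(!nzchar(conds))) {
    abort_data("profiles must be named numeric vectors (condition -> log2FC)")
  }
  ok <- vapply(cluster_profiles, function(p) identical(names(p), conds), logical(1))
  if (!all(ok)) abort_data("profiles have mismatched condition sets")
  if (is.null(names(cluster_profiles))) {
    names(cluster_profiles) <- seq_along(cluster_profiles)
  }
  sizes <- rep_len(as.integer(genes_per_cluster), length(cluster_profiles))
  n <- sum(sizes)
  gene_id <- sprintf("g%05d", seq_len(n))
  cluster <- rep(seq_along(cluster_profiles), sizes)

  base <- do.call(rbind, cluster_profiles)[cluster, , drop = FALSE]
  fc <- with_seed(noise$seed, {
    base + matrix(rnorm(n * length(conds), 0, noise$fc_noise_sd), n, length(conds))
  })
  dimnames(fc) <- list(gene_id, conds)

  structure(list(
    fc = matrix_to_tibble(fc),
    truth = tibble::tibble(gene_id = gene_id, cluster = cluster,
                           profile = names(cluster_profiles)[cluster])
  ), class = "fc_sim")
}

#' Derive pairwise contrast tables from a count matrix
#'
#' A deliberately simple stand-in for a full differential-expression model,
#' used to exercise the downstream enrichment-calling logic on synthetic
#' counts (real studies supply contrast tables from DESeq2 or similar; this
#' is not such a model). Counts are library-size normalized by total-count
#' scaling; for every ordered pair of populations within a tissue-layer
#' group the log2 fold change of pseudocounted group means is reported
#' together with a Benjamini-Hochberg-adjusted p-value from a Welch t-test
#' on log2(normalized count + 1), adjusted per contrast.
#'
#' @param counts Count table: `gene_id` + one column per sample, sample names
#'   `<population>.r<i>` as produced by [generate_celltype_counts()] (a
#'   `celltype_sim` is also accepted).
#' @param design The matching [population_design()].
#' @param pseudocount Added before log2; default 1.
#' @return A contrast tibble with columns `gene_id`, `contrast`
#'   (`"A_vs_B"`, meaning log2(A/B)), `log2fc`, `padj`.
#' @export
contrasts_from_counts <- function(counts, design, pseudocount = 1) {
  if (inherits(counts, "celltype_sim")) counts <- counts$counts
  design <- as_population_design(design)
  check_gene_table(counts, "count table")
  m <- gene_matrix(counts)
  if (any(m < 0) || any(m != round(m))) abort_data("counts must be nonnegative integers")

  samples <- design_samples(design)
  missing <- setdiff(samples$sample, colnames(m))
  if (length(missing)) {
    abort_data(paste0("count table lacks sample column(s): ",
                      paste(head(missing, 3), collapse = ", ")))
  }
  m <- m[, samples$sample, drop = FALSE]

  libsize <- colSums(m)
  norm <- sweep(m, 2, libsize / mean(libsize), "/")
  lognorm <- log2(norm + pseudocount)

  pop_cols <- split(seq_len(nrow(samples)), samples$population)[design$population]
  usable <- design$population[vapply(pop_cols, length, integer(1)) >= 2L]
  dropped <- setdiff(design$population, usable)
  if (length(dropped)) {
    warning("contrast(s) skipped for population(s) with <2 replicates: ",
            paste(dropped, collapse = ", "))
  }

  res <- list()
  for (grp in unique(design$group)) {
    pops <- intersect(design$population[design$group == grp], usable)
    for (a in pops) for (b in setdiff(pops, a)) {
      ca <- pop_cols[[a]]; cb <- pop_cols[[b]]
      lfc <- log2((rowMeans(norm[, ca, drop = FALSE]) + pseudocount) /
                    (rowMeans(norm[, cb, drop = FALSE]) + pseudocount))
      p <- vapply(seq_len(nrow(m)), function(i) {
        tryCatch(t.test(lognorm[i, ca], lognorm[i, cb])$p.value,
                 error = function(e) NA_real_)
      }, numeric(1))
      res[[paste0(a, "_vs_", b)]] <- tibble::tibble(
        gene_id = rownames(m),
        contrast = paste0(a, "_vs_", b),
        log2fc = unname(lfc),
        padj = p.adjust(p, method = "BH")
      )
    }
  }
  dplyr::bind_rows(res)
}

#' Generate a gene-set annotation with one planted term
#'
#' Builds a GMT-expressible term -> gene-set map over a given universe: one
#' term is exactly the supplied planted subset, the remaining terms are
#' uniform random draws of sizes sampled from `term_size_range`. Used to
#' test that enrichment analysis ranks a truly enriched term first.
#'
#' @param universe Character vector of gene ids.
#' @param n_terms Total number of terms (>= 1; includes the planted one when
#'   supplied).
#' @param planted_term `NULL`, or a list with `term` (id) and `genes`
#'   (character subset of `universe`).
#' @param term_size_range Integer length-2 range of background term sizes.
#' @param seed Integer seed.
#' @return A `gene_set_annotation` tibble (`term`, `description`, list-column
#'   `genes`) with the universe stored in `attr(, "universe")`.
#' @export
generate_annotation <- function(universe, n_terms, planted_term = NULL,
                                term_size_range = c(10L, 50L), seed = 1L) {
  universe <- unique(as.character(universe))
  stopifnot(n_terms >= 1)
  if (!is.null(planted_term)) {
    outside <- setdiff(planted_term$genes, universe)
    if (length(outside)) {
      abort_data(paste0("planted term contains ids outside the universe: ",
                        paste(head(outside, 3), collapse = ", ")))
    }
  }
  n_bg <- n_terms - !is.null(planted_term)
  if (n_bg < 0) abort_data("n_terms must cover the planted term")
  sizes_max <- min(term_size_range[2], length(universe))
  sizes_min <- min(term_size_range[1], sizes_max)

  bg <- with_seed(as.integer(seed), {
    lapply(seq_len(n_bg), function(i) {
      sort(sample(universe, sample(seq(sizes_min, sizes_max), 1)))
    })
  })
  terms <- tibble::tibble(
    term = c(if (!is.null(planted_term)) planted_term$term,
             sprintf("BG%04d", seq_len(n_bg))),
    description = c(if (!is.null(planted_term)) "planted term",
                    rep("background term", n_bg)),
    genes = c(if (!is.null(planted_term)) list(sort(unique(planted_term$genes))),
              bg)
  )
  if (anyDuplicated(terms$term)) abort_data("term ids must be unique")
  structure(terms, universe = universe,
            class = c("gene_set_annotation", class(terms)))
}
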
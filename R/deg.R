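#' Call cell-type-enriched genes from pairwise contrasts
#'
#' Implements the within-group one-vs-each rule for cell-type enrichment: a
#' gene is enriched in population P if, for at least one of P's two pairwise
#' contrasts against the other populations of its group, the log2 fold
#' change exceeds `lfc_min` and the adjusted p-value is below `padj_max`.
#' Contrasts are named `"A_vs_B"` (log2(A/B)); missing orientations are
#' derived by sign flip from the reverse contrast. `NA` adjusted p-values
#' are treated as not significant.
#'
#' @param contrasts Contrast tibble: `gene_id`, `contrast`, `log2fc`, `padj`.
#' @param lfc_min Log2 fold-change threshold (default 1).
#' @param padj_max Adjusted p-value threshold (default 0.05).
#' @param strict If `TRUE` (default) the fold-change comparison is strict
#'   (`log2fc > lfc_min`); set `FALSE` for `>=`.
#' @return An `enriched_sets` tibble (`population`, `gene_id`), with the
#'   thresholds and the populations actually called stored as attributes.
#' @examples
#' ct <- tibble::tibble(gene_id = "g1", contrast = "REV_vs_KAN1",
#'                      log2fc = 1.5, padj = 0.01)
#' call_enriched(ct)
#' @export
call_enriched <- function(contrasts, lfc_min = 1, padj_max = 0.05, strict = TRUE) {
  req <- c("gene_id", "contrast", "log2fc", "padj")
  if (!is.data.frame(contrasts) || !all(req %in% names(contrasts))) {
    abort_data("contrasts must have columns gene_id, contrast, log2fc, padj")
  }
  if (any(!is.na(contrasts$padj) & (contrasts$padj < 0 | contrasts$padj > 1))) {
    abort_data("padj values must lie in [0, 1]")
  }
  parts <- strsplit(contrasts$contrast, "_vs_", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort_data("contrast names must follow 'A_vs_B'")
  }
  tab <- dplyr::mutate(tibble::as_tibble(contrasts[req]),
                       pop_a = vapply(parts, `[`, "", 1L),
                       pop_b = vapply(parts, `[`, "", 2L))
  # mirror orientations that are only present one way
  have <- unique(tab$contrast)
  mirrored <- dplyr::filter(tab, !paste0(.data$pop_b, "_vs_", .data$pop_a) %in% have)
  mirrored <- dplyr::mutate(mirrored,
                            log2fc = -.data$log2fc,
                            tmp = .data$pop_a, pop_a = .data$pop_b,
                            pop_b = .data$tmp, tmp = NULL,
                            contrast = paste0(.data$pop_a, "_vs_", .data$pop_b))
  tab <- dplyr::bind_rows(tab, mirrored)

  partners <- tapply(tab$pop_b, tab$pop_a, function(x) length(unique(x)))
  pops <- names(partners)[partners >= 2L]
  skipped <- setdiff(names(partners), pops)
  if (length(skipped)) {
    warning("population(s) skipped, missing within-group contrast(s): ",
            paste(skipped, collapse = ", "))
  }

  fc_ok <- if (strict) tab$log2fc > lfc_min else tab$log2fc >= lfc_min
  hit <- fc_ok & !is.na(tab$padj) & tab$padj < padj_max & tab$pop_a %in% pops
  out <- dplyr::distinct(
    dplyr::arrange(
      tibble::tibble(population = tab$pop_a[hit], gene_id = tab$gene_id[hit]),
      .data$population, .data$gene_id))
  structure(out,
            populations = pops, lfc_min = lfc_min, padj_max = padj_max,
            strict = strict,
            class = c("enriched_sets", class(out)))
}

#' Classify enriched genes of one group into six Venn sectors
#'
#' Given the enriched sets of the three populations of one tissue-layer
#' group, assigns every enriched gene to exactly one of six exclusive
#' sectors: one per single population (`"<pop>-only"`) and one per pairwise
#' overlap (`"<popA>+<popB>"`). A gene enriched in all three populations is
#' inconsistent with the one-vs-each rule and raises an error naming the
#' gene.
#'
#' @param enriched An `enriched_sets` tibble covering exactly three
#'   populations (see [call_enriched()]).
#' @return A tibble (`gene_id`, `sector`) whose sectors are disjoint and
#'   jointly cover every enriched gene.
#' @export
classify_sectors <- function(enriched) {
  pops <- attr(enriched, "populations")
  if (is.null(pops)) pops <- sort(unique(enriched$population))
  if (length(pops) != 3L) {
    abort_data("sector classification needs exactly three populations")
  }
  memb <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(tibble::as_tibble(enriched)), .data$gene_id),
    pops = list(sort(unique(.data$population))), .groups = "drop")
  triple <- memb$gene_id[lengths(memb$pops) >= 3L]
  if (length(triple)) {
    abort_data(paste0("gene(s) enriched in all three populations: ",
                      paste(head(triple, 5), collapse = ", ")))
  }
  sector <- vapply(memb$pops, function(p) {
    if (length(p) == 1L) paste0(p, "-only") else paste(p, collapse = "+")
  }, character(1))
  dplyr::arrange(tibble::tibble(gene_id = memb$gene_id, sector = sector),
                 .data$sector, .data$gene_id)
}

#' Summarize cluster expression relative to a reference population
#'
#' For each cluster and each population, averages over the cluster's member
#' genes the ratio of the gene's mean expression in that population to its
#' mean expression in the reference population (so the reference column is
#' identically 1), reproducing the "expression relative to BFP-only cells"
#' style of summary.
#'
#' @param expr Expression tibble: `gene_id` + one numeric column of mean
#'   expression per population; the reference column must be strictly
#'   positive.
#' @param clusters Cluster assignment tibble (`gene_id`, `cluster`).
#' @param reference Name of the reference population column.
#' @return A tibble with `cluster` and one relative-expression column per
#'   population.
#' @export
summarize_cluster_expression <- function(expr, clusters, reference) {
  check_gene_table(expr, "expression table")
  pops <- setdiff(names(expr), "gene_id")
  if (!reference %in% pops) {
    abort_data(paste0("reference population not in expression table: ", reference))
  }
  if (any(expr[[reference]] <= 0)) {
    abort_data("reference expression must be strictly positive")
  }
  empty <- setdiff(unique(clusters$cluster),
                   unique(clusters$cluster[clusters$gene_id %in% expr$gene_id]))
  if (length(empty)) {
    warning("cluster(s) with no member in the expression table omitted: ",
            paste(empty, collapse = ", "))
  }
  dat <- dplyr::inner_join(clusters[c("gene_id", "cluster")], expr, by = "gene_id")
  dat <- dplyr::mutate(dat, dplyr::across(dplyr::all_of(pops),
                                          ~ .x / dat[[reference]]))
  dplyr::arrange(
    dplyr::summarise(dplyr::group_by(dat, .data$cluster),
                     dplyr::across(dplyr::all_of(pops), mean), .groups = "drop"),
    .data$cluster)
}

#' Label clusters preferentially expressed in particular populations
#'
#' A cluster is called preferential for population P when its summarized
#' relative expression in P is at least `fold_cutoff` times the minimum
#' across populations. Several populations can qualify together; the
#' minimum population never does, so a cluster is never preferential
#' everywhere.
#'
#' @param summary Output of [summarize_cluster_expression()].
#' @param fold_cutoff Preferential-expression ratio cutoff (default 1.5).
#' @return A tibble (`cluster`, `preferred`) where `preferred` is `"none"`
#'   or a `+`-joined list of populations.
#' @export
preferential_call <- function(summary, fold_cutoff = 1.5) {
  pops <- setdiff(names(summary), "cluster")
  vals <- as.matrix(summary[pops])
  if (any(vals <= 0)) abort_data("summary values must be positive")
  preferred <- apply(vals, 1, function(v) {
    hit <- pops[v >= fold_cutoff * min(v)]
    if (length(hit)) paste(sort(hit), collapse = "+") else "none"
  })
  tibble::tibble(cluster = summary$cluster, preferred = unname(preferred))
}
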
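#' Hypergeometric term enrichment with over-representation filters
#'
#' Classic one-sided hypergeometric (Fisher) enrichment of a query gene set
#' against each annotated term, followed by the reporting filters used for
#' GO tables in cell-type profiling studies: raw p-value below `p_cutoff`,
#' at least `min_overrep` over-represented (query-overlapping) genes, and at
#' least `min_annotated` genes annotated in the universe. Note this is the
#' classic per-term test, not a hierarchy-aware (elim/weight) algorithm — no
#' GO-DAG structure is used — and, matching the filter-based reporting it
#' reproduces, p-values are not multiplicity-adjusted.
#'
#' @param query Character vector of gene ids, a subset of `universe`.
#' @param universe Character vector: all considered genes (typically every
#'   gene detected in the tissue).
#' @param annotation A `gene_set_annotation` ([generate_annotation()],
#'   [read_gmt()]) or named list of gene-id vectors.
#' @param p_cutoff,min_overrep,min_annotated Reporting filters (defaults
#'   0.05 / 5 / 5).
#' @return Tibble (`term`, `description`, `n_annotated`, `n_overrep`,
#'   `expected`, `p_value`) of passing terms, ascending in p; the unfiltered
#'   table is attached as `attr(, "all_terms")`.
#' @examples
#' ann <- generate_annotation(sprintf("g%03d", 1:100), n_terms = 5,
#'                            planted_term = list(term = "T", genes = sprintf("g%03d", 1:10)),
#'                            seed = 3)
#' term_enrichment(sprintf("g%03d", 1:10), sprintf("g%03d", 1:100), ann)
#' @export
term_enrichment <- function(query, universe, annotation, p_cutoff = 0.05,
                            min_overrep = 5L, min_annotated = 5L) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(query) || !length(universe)) {
    abort_data("query and universe must be non-empty")
  }
  outside <- setdiff(query, universe)
  if (length(outside)) {
    abort_data(paste0("query gene(s) outside the universe: ",
                      paste(head(outside, 3), collapse = ", ")))
  }
  sets <- annotation_sets(annotation)

  N <- length(universe)
  n <- length(query)
  res <- purrr::imap_dfr(sets$genes_by_term, function(genes, term) {
    ann <- intersect(genes, universe)
    K <- length(ann)
    if (K == 0L) return(NULL)  # term with zero universe overlap: skipped
    k <- length(intersect(ann, query))
    tibble::tibble(
      term = term,
      description = sets$description[[term]],
      n_annotated = K,
      n_overrep = k,
      expected = n * K / N,
      p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  if (!nrow(res)) return(res)
  res <- dplyr::arrange(res, .data$p_value, .data$term)
  keep <- dplyr::filter(res, .data$p_value < p_cutoff,
                        .data$n_overrep >= min_overrep,
                        .data$n_annotated >= min_annotated)
  attr(keep, "all_terms") <- res
  keep
}

# normalize annotation input to list(genes_by_term = named list, description)
annotation_sets <- function(annotation) {
  if (is.data.frame(annotation) && all(c("term", "genes") %in% names(annotation))) {
    desc <- if ("description" %in% names(annotation)) {
      setNames(annotation$description, annotation$term)
    } else setNames(annotation$term, annotation$term)
    list(genes_by_term = setNames(annotation$genes, annotation$term),
         description = as.list(desc))
  } else if (is.list(annotation) && !is.null(names(annotation))) {
    list(genes_by_term = annotation,
         description = as.list(setNames(names(annotation), names(annotation))))
  } else {
    abort_data("annotation must be a gene_set_annotation or named list of gene sets")
  }
}

#' Overlap counts and percentages of query sets across categories
#'
#' For each labelled query gene set, counts its members falling in each of a
#' collection of disjoint categories (e.g. cell-type-enriched sets or Venn
#' sectors) and expresses them as percentages of the query's categorized
#' members. When a `background` set is given, an `"all"` query row is added
#' as the baseline the other rows should be compared against. Percentages
#' are exact here; rounding to whole numbers is presentation-only
#' (`format_overlap_table()`).
#'
#' @param query_sets Named list of gene-id vectors.
#' @param categories Named list of pairwise-disjoint gene-id vectors.
#' @param background Optional gene-id vector for the `"all"` baseline row.
#' @return Tibble (`query`, `category`, `n`, `percent`) where `percent` is
#'   100 * n / (query's categorized genes).
#' @export
overlap_percentages <- function(query_sets, categories, background = NULL) {
  stopifnot(is.list(query_sets), is.list(categories),
            !is.null(names(query_sets)), !is.null(names(categories)))
  all_cat <- unlist(categories, use.names = FALSE)
  if (anyDuplicated(all_cat)) {
    abort_data("categories must be disjoint")
  }
  if (!is.null(background)) {
    query_sets <- c(list(all = unique(as.character(background))), query_sets)
  }
  purrr::imap_dfr(query_sets, function(q, lab) {
    q <- unique(as.character(q))
    n_cat <- vapply(categories, function(cat) length(intersect(q, cat)), integer(1))
    tot <- sum(n_cat)
    tibble::tibble(query = lab, category = names(categories),
                   n = unname(n_cat),
                   percent = if (tot > 0) 100 * unname(n_cat) / tot else rep(0, length(n_cat)))
  })
}

#' Render an overlap table with whole-number percentages
#'
#' Presentation helper: pivots the output of [overlap_percentages()] to a
#' query x category table of percentages rounded to the nearest whole
#' number (rounding happens only here, never in the computation).
#'
#' @param overlap Output of [overlap_percentages()].
#' @return A wide tibble of rounded percentages.
#' @export
format_overlap_table <- function(overlap) {
  tidyr::pivot_wider(
    dplyr::mutate(overlap, percent = round(.data$percent)),
    id_cols = "query", names_from = "category", values_from = "percent")
}

#' Cross-tabulate co-regulation between two regulators
#'
#' For the genes differentially regulated by both of two regulators at one
#' time point, computes the fractions that are co-induced (up by both),
#' co-repressed (down by both), or oppositely regulated. Fractions are of
#' the regulator-pair intersection and sum to 1.
#'
#' @param deg_sets Tibble with columns `regulator`, `direction` (`"up"` /
#'   `"down"`) and `gene_id` (one row per regulated gene), for a single time
#'   point; exactly two regulators.
#' @return One-row tibble: `n_shared`, `co_induced`, `co_repressed`,
#'   `opposite` (fractions), plus the regulator names.
#' @export
coregulation_table <- function(deg_sets) {
  req <- c("regulator", "direction", "gene_id")
  if (!is.data.frame(deg_sets) || !all(req %in% names(deg_sets))) {
    abort_data("deg_sets must have columns regulator, direction, gene_id")
  }
  if (!all(deg_sets$direction %in% c("up", "down"))) {
    abort_data("direction must be 'up' or 'down'")
  }
  regs <- unique(deg_sets$regulator)
  if (length(regs) != 2L) abort_data("need exactly two regulators")
  dup <- dplyr::count(dplyr::distinct(deg_sets), .data$regulator, .data$gene_id)
  if (any(dup$n > 1)) {
    bad <- dup$gene_id[dup$n > 1][1]
    abort_data(paste0("gene both up- and down-regulated for one regulator: ", bad))
  }
  dir_of <- function(r) setNames(
    deg_sets$direction[deg_sets$regulator == r],
    deg_sets$gene_id[deg_sets$regulator == r])
  a <- dir_of(regs[1]); b <- dir_of(regs[2])
  shared <- intersect(names(a), names(b))
  n <- length(shared)
  co_up <- sum(a[shared] == "up" & b[shared] == "up")
  co_down <- sum(a[shared] == "down" & b[shared] == "down")
  tibble::tibble(regulator_a = regs[1], regulator_b = regs[2],
                 n_shared = n,
                 co_induced = if (n) co_up / n else 0,
                 co_repressed = if (n) co_down / n else 0,
                 opposite = if (n) (n - co_up - co_down) / n else 0)
}
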
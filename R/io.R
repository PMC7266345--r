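#' Read and write the pipeline's tabular formats
#'
#' All tabular formats are plain TSV, LF line endings, UTF-8: contrast
#' tables (`gene_id`, `contrast`, `log2fc`, `padj`), gene x condition
#' matrices (`gene_id` first column), cluster assignments (`gene_id`,
#' `cluster`, with `unclustered` for genes outside any cluster), enriched
#' sets (`gene_id`, `population`), weighted edge lists (`from`, `to`,
#' `weight`), newline-delimited gene lists, and GMT gene-set files.
#' Readers validate structure (duplicate gene ids and non-numeric values
#' are rejected; malformed rows are reported with their line number) and
#' writers round-trip byte-identically.
#'
#' @param path File path.
#' @param x Object to write (tibble of the respective shape).
#' @return Readers return tibbles (or a `gene_set_annotation`); writers
#'   return `x` invisibly.
#' @name samclust_io
NULL

read_tsv_checked <- function(path, col_types, what) {
  df <- readr::read_tsv(path, col_types = col_types, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort_data(sprintf("malformed %s row at line %d of %s: expected %s",
                       what, probs$row[1], path, probs$expected[1]))
  }
  missing <- setdiff(names(col_types$cols), names(df))
  if (length(missing)) {
    abort_data(paste0(what, " is missing column(s): ",
                      paste(missing, collapse = ", ")))
  }
  df
}

#' @rdname samclust_io
#' @export
read_contrast_table <- function(path) {
  ct <- readr::cols(gene_id = readr::col_character(),
                    contrast = readr::col_character(),
                    log2fc = readr::col_double(),
                    padj = readr::col_double())
  df <- read_tsv_checked(path, ct, "contrast table")
  if (anyDuplicated(df[c("gene_id", "contrast")])) {
    abort_data("duplicate (gene_id, contrast) record in contrast table")
  }
  df
}

#' @rdname samclust_io
#' @export
write_contrast_table <- function(x, path) {
  readr::write_tsv(x[c("gene_id", "contrast", "log2fc", "padj")], path)
  invisible(x)
}

#' @rdname samclust_io
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort_data(sprintf("non-numeric value at line %d of %s",
                       probs$row[1], path))
  }
  check_gene_table(df, basename(path))
  df
}

#' @rdname samclust_io
#' @export
write_matrix_tsv <- function(x, path) {
  check_gene_table(x, "matrix")
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname samclust_io
#' @export
read_cluster_assignment <- function(path) {
  df <- read_tsv_checked(path, readr::cols(
    gene_id = readr::col_character(),
    cluster = readr::col_character()), "cluster assignment")
  if (anyDuplicated(df$gene_id)) abort_data("duplicate gene id in assignment")
  bad <- !df$cluster %in% "unclustered" & is.na(suppressWarnings(as.integer(df$cluster)))
  if (any(bad)) {
    abort_data(sprintf("invalid cluster label at line %d", which(bad)[1] + 1L))
  }
  tibble::tibble(gene_id = df$gene_id,
                 cluster = suppressWarnings(as.integer(df$cluster)))
}

#' @rdname samclust_io
#' @export
write_cluster_assignment <- function(x, path) {
  out <- tibble::tibble(
    gene_id = x$gene_id,
    cluster = ifelse(is.na(x$cluster), "unclustered", as.character(x$cluster)))
  readr::write_tsv(out, path)
  invisible(x)
}

#' @rdname samclust_io
#' @export
read_enriched_sets <- function(path) {
  df <- read_tsv_checked(path, readr::cols(
    gene_id = readr::col_character(),
    population = readr::col_character()), "enriched sets")
  out <- dplyr::arrange(df[c("population", "gene_id")],
                        .data$population, .data$gene_id)
  structure(out, populations = sort(unique(out$population)),
            class = c("enriched_sets", class(out)))
}

#' @rdname samclust_io
#' @export
write_enriched_sets <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x)[c("gene_id", "population")], path)
  invisible(x)
}

#' @rdname samclust_io
#' @export
read_edge_list <- function(path) {
  read_tsv_checked(path, readr::cols(from = readr::col_character(),
                                     to = readr::col_character(),
                                     weight = readr::col_double()),
                   "edge list")
}

#' @rdname samclust_io
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "consensus_graph")) {
    el <- igraph::as_data_frame(x$graph, what = "edges")
    x <- tibble::tibble(from = el$from, to = el$to, weight = el$weight)
  }
  readr::write_tsv(x[c("from", "to", "weight")], path)
  invisible(x)
}

#' @rdname samclust_io
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path, encoding = "UTF-8")
  ids[nzchar(ids)]
}

#' @rdname samclust_io
#' @export
write_gene_list <- function(x, path) {
  writeLines(as.character(x), path, sep = "\n")
  invisible(x)
}

#' @rdname samclust_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort_data(sprintf("GMT line %d has fewer than 3 tab-separated fields",
                       short[1]))
  }
  terms <- tibble::tibble(
    term = vapply(fields, `[`, "", 1L),
    description = vapply(fields, `[`, "", 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
  if (anyDuplicated(terms$term)) abort_data("duplicate term id in GMT file")
  structure(terms, universe = sort(unique(unlist(terms$genes))),
            class = c("gene_set_annotation", class(terms)))
}

#' @rdname samclust_io
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(x$term[i], x$description[i], x$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(x)
}
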
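#' Derive a per-stage random seed from a master seed
#'
#' All stochastic stages take explicit seeds; pipelines derive stage seeds
#' from one master seed with fixed offsets so that stages are reproducible
#' independently of execution order.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer stage/iteration index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(index))
  # Weyl-style mixing; kept in double to avoid 32-bit overflow, then reduced
  as.integer((abs(master) * 2654435761 + index * 40503 + 12345) %% 2147483629)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

abort_data <- function(msg) {
  rlang::abort(msg, class = "samclust_data_error")
}

# shared validator: a fold-change / expression table is a data frame whose
# first column is `gene_id` (unique character) and remaining columns numeric
check_gene_table <- function(df, what = "table") {
  if (!is.data.frame(df)) abort_data(paste0(what, " must be a data frame"))
  if (!"gene_id" %in% names(df)) {
    abort_data(paste0(what, " must have a `gene_id` column"))
  }
  if (anyDuplicated(df$gene_id)) {
    dup <- df$gene_id[duplicated(df$gene_id)][1]
    abort_data(paste0("duplicate gene id in ", what, ": ", dup))
  }
  num_cols <- setdiff(names(df), "gene_id")
  bad <- num_cols[!vapply(df[num_cols], is.numeric, logical(1))]
  if (length(bad)) {
    abort_data(paste0("non-numeric column(s) in ", what, ": ",
                      paste(bad, collapse = ", ")))
  }
  invisible(df)
}

# gene-table -> numeric matrix with gene ids as rownames
gene_matrix <- function(df) {
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_tibble <- function(m, id_col = "gene_id") {
  tibble::as_tibble(m, rownames = id_col)
}
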
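#' Quantile-normalize a fold-change matrix
#'
#' Forces every condition column to share one value distribution: after the
#' transform, each column's sorted values equal the per-rank across-column
#' means (ties receive the average of the means over their rank range) while
#' within-column order is preserved. Missing entries — genes not significant
#' in some condition — are filled with `missing_fill` (default 0: a
#' non-response is a zero fold change) before normalization. The transform
#' is idempotent.
#'
#' @param fc Fold-change tibble: `gene_id` + one numeric column per
#'   condition.
#' @param missing_fill Value substituted for `NA` entries before
#'   normalization (set to `NULL` to forbid missing values instead).
#' @return The normalized tibble, flagged with `attr(, "normalized") = TRUE`.
#' @examples
#' fc <- tibble::tibble(gene_id = c("a", "b"), c1 = c(1, 2), c2 = c(3, 4))
#' quantile_normalize(fc)
#' @export
quantile_normalize <- function(fc, missing_fill = 0) {
  check_gene_table(fc, "fold-change matrix")
  m <- gene_matrix(fc)
  if (anyNA(m)) {
    if (is.null(missing_fill)) abort_data("fold-change matrix contains NA")
    m[is.na(m)] <- missing_fill
  }
  if (ncol(m) < 2L) {
    warning("single-column matrix: quantile normalization is a no-op")
    out <- matrix_to_tibble(m)
  } else {
    out <- matrix_to_tibble(limma::normalizeQuantiles(m, ties = TRUE))
  }
  attr(out, "normalized") <- TRUE
  out
}
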
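#' Define the FACS population design
#'
#' Describes the sorted cell populations of a cell-type profiling experiment:
#' population labels, the tissue-layer group each belongs to, and the number
#' of biological replicates per population. The default reproduces the
#' six-way SAM sort: epidermal cells positive for the REV or KAN1 reporter,
#' epidermal cells carrying only the BFP layer marker, their sub-epidermal
#' counterparts, and the all-negative sub-epidermal pool. Enrichment calling
#' compares populations only within their group (epidermal vs sub-epidermal).
#'
#' @param populations Character vector of unique population labels.
#' @param groups Character vector, same length, assigning each population to
#'   a group.
#' @param n_replicates Integer (length 1 or one per population): biological
#'   replicates; at least 2 each.
#' @return A `population_design` tibble with columns `population`, `group`,
#'   `n_replicates`.
#' @examples
#' population_design()
#' @export
population_design <- function(populations = c("epidermal-REV", "epidermal-KAN1",
                                              "epidermal-BFP-only",
                                              "subepidermal-REV", "subepidermal-KAN1",
                                              "all-negative"),
                              groups = c("epidermal", "epidermal", "epidermal",
                                         "subepidermal", "subepidermal", "subepidermal"),
                              n_replicates = 3L) {
  if (anyDuplicated(populations)) abort_data("population names must be unique")
  if (length(groups) != length(populations)) {
    abort_data("every population needs exactly one group")
  }
  if (any(is.na(groups) | !nzchar(groups))) {
    abort_data("invalid design: population without group")
  }
  n_replicates <- as.integer(rep_len(n_replicates, length(populations)))
  if (any(n_replicates < 2L)) abort_data("each population needs >= 2 replicates")
  structure(
    tibble::tibble(population = as.character(populations),
                   group = as.character(groups),
                   n_replicates = n_replicates),
    class = c("population_design", class(tibble::tibble()))
  )
}

as_population_design <- function(x) {
  if (inherits(x, "population_design")) return(x)
  if (!is.data.frame(x) || !all(c("population", "group") %in% names(x))) {
    abort_data("expected a population_design (see population_design())")
  }
  population_design(x$population, x$group,
                    if ("n_replicates" %in% names(x)) x$n_replicates else 3L)
}

# sample labels "<population>.r<i>", in design order
design_samples <- function(design) {
  tibble::tibble(
    sample = unlist(purrr::map2(design$population, design$n_replicates,
                                ~ paste0(.x, ".r", seq_len(.y)))),
    population = rep(design$population, design$n_replicates)
  ) |>
    dplyr::left_join(design[, c("population", "group")], by = "population")
}

#' Specify the stochastic model behind the synthetic-data generators
#'
#' Counts are simulated as negative binomial draws around log-normal baseline
#' means (a standard bulk RNA-seq emulation); fold-change matrices add i.i.d.
#' Gaussian noise to planted cluster profiles. All generators are pure
#' functions of their arguments including `seed`.
#'
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline mean counts (defaults give a median of ~55 counts with a long
#'   right tail, typical of moderately sequenced bulk libraries).
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); must be > 0.
#' @param fc_noise_sd Standard deviation (log2 units) of the Gaussian noise
#'   added to planted log2 fold-change profiles; must be >= 0.
#' @param seed Integer seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(baseline_meanlog = 4, baseline_sdlog = 1.5,
                        dispersion = 0.1, fc_noise_sd = 0.3, seed = 1L) {
  stopifnot(dispersion > 0, fc_noise_sd >= 0)
  structure(list(baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 fc_noise_sd = fc_noise_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}
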
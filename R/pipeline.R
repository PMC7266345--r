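pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "samclust_run",
    stages = c("simulate", "call_degs", "cluster", "enrich", "summarize"),
    inputs = list(contrast_table = NULL, fc_matrix = NULL, gmt = NULL,
                  expression = NULL),
    simulate = list(
      n_genes = 300L, frac_enriched = 0.2, effect_size = 2,
      n_replicates = 6L, dispersion = 0.1, fc_noise_sd = 0.4,
      baseline_meanlog = 4, baseline_sdlog = 1.5,
      genes_per_cluster = 60L,
      profiles = list(
        rev_up       = list(REV_6h = 2,    REV_16h = 2,    KAN1_6h = 0,  KAN1_16h = 0),
        rev_down     = list(REV_6h = -2,   REV_16h = -2,   KAN1_6h = 0,  KAN1_16h = 0),
        rev_transient = list(REV_6h = 1.7, REV_16h = -1.4, KAN1_6h = 0,  KAN1_16h = 0),
        kan1_up      = list(REV_6h = 0,    REV_16h = 0,    KAN1_6h = 2,  KAN1_16h = 2),
        kan1_down    = list(REV_6h = 0,    REV_16h = 0,    KAN1_6h = -2, KAN1_16h = -2)),
      n_terms = 20L, term_size_range = c(10L, 50L)),
    thresholds = list(lfc_min = 1, padj_max = 0.05, strict = TRUE,
                      fold_cutoff = 1.5),
    ensemble = list(n_iterations = 4000L, k_min = 3L, subsample_min_frac = 0.8,
                    kmeans_max_iter = 500L, kmeans_restarts = 20L),
    cluster = list(retain_frac = 0.65, n_trials = 1000L, damping = 0.85),
    enrich = list(p_cutoff = 0.05, min_overrep = 5L, min_annotated = 5L)
  )
}

check_config_keys <- function(cfg, defaults, prefix = "") {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    rlang::abort(paste0("unknown config field: ", prefix, unknown[1]),
                 class = "samclust_config_error")
  }
  for (key in names(cfg)) {
    # `profiles` and `inputs` carry free-form names below this level
    if (key %in% c("profiles", "term_size_range", "stages", "inputs")) next
    if (is.list(defaults[[key]]) && is.list(cfg[[key]])) {
      check_config_keys(cfg[[key]], defaults[[key]], paste0(prefix, key, "."))
    }
  }
  invisible(cfg)
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the pipeline defaults and validates them:
#' unknown fields are rejected (classed `samclust_config_error`) and stage
#' names checked. The configuration can come from a YAML or JSON file whose
#' structure mirrors the argument list of each stage (the `ensemble` block
#' mirrors [ensemble_config()] field names).
#'
#' @param config A (possibly nested, possibly partial) list of settings, or
#'   the path to a YAML/JSON file containing one.
#' @return The complete validated configuration list, classed
#'   `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (inherits(config, "pipeline_config")) return(config)
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  check_config_keys(config, defaults)
  cfg <- modifyList(defaults, config)
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad)) {
    rlang::abort(paste0("unknown stage: ", bad[1]),
                 class = "samclust_config_error")
  }
  cfg$stages <- intersect(defaults$stages, cfg$stages)  # canonical order
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — `simulate` (synthetic counts,
#' contrast tables, fold-change matrix, GMT annotation with planted truth),
#' `call_degs` (enrichment calling and six-sector classification),
#' `cluster` (consensus clustering of the fold-change matrix), `enrich`
#' (per-cluster term enrichment) and `summarize` (relative cluster
#' expression, preferential-expression calls and cluster x sector overlap
#' table) — writing every result as TSV/GMT under `outdir` and finishing
#' with a JSON run manifest recording the configuration, per-stage wall
#' clock, md5 digests of every output, and recovery statistics where
#' planted truth is available. Identical configuration and seed give
#' byte-identical outputs. If a stage fails its partial outputs are renamed
#' with a `.partial` suffix before the error propagates.
#'
#' @param config A [pipeline_config()], a settings list, or a YAML/JSON
#'   path.
#' @return The manifest (list), invisibly; also written to
#'   `outdir/manifest.json`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(cfg$outdir, f)
  manifest <- list(config = unclass(cfg), stages = list(), stats = list(),
                   versions = list(samclust = as.character(utils::packageVersion("samclust")),
                                   R = paste(R.version$major, R.version$minor, sep = ".")))
  written <- character()

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible())
    t0 <- proc.time()[["elapsed"]]
    before <- written
    res <- tryCatch(fun(), error = function(e) {
      new_files <- setdiff(written, before)
      for (f in new_files) if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      rlang::abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                   class = "samclust_stage_error", parent = e)
    })
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  emit <- function(x, file, writer) {
    writer(x, path(file))
    written <<- c(written, path(file))
    x
  }

  sim <- cfg$simulate
  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    noise_counts <- noise_model(sim$baseline_meanlog, sim$baseline_sdlog,
                                sim$dispersion, sim$fc_noise_sd,
                                seed = derive_seed(cfg$seed, 101L))
    cts <- generate_celltype_counts(population_design(n_replicates = sim$n_replicates),
                                    sim$n_genes, sim$frac_enriched,
                                    sim$effect_size, noise_counts)
    emit(cts$counts, "counts.tsv", write_matrix_tsv)
    emit(cts$truth, "truth_counts.tsv", function(x, p) readr::write_tsv(x, p))
    contrasts <- contrasts_from_counts(cts, cts$design)
    emit(contrasts, "contrast_table.tsv", write_contrast_table)

    profiles <- lapply(sim$profiles, function(p) unlist(p))
    noise_fc <- noise_model(fc_noise_sd = sim$fc_noise_sd, dispersion = sim$dispersion,
                            seed = derive_seed(cfg$seed, 102L))
    fcs <- generate_foldchange_matrix(profiles, sim$genes_per_cluster, noise_fc)
    emit(fcs$fc, "fc_matrix.tsv", write_matrix_tsv)
    emit(fcs$truth, "truth_fc.tsv", function(x, p) readr::write_tsv(x, p))

    planted_genes <- fcs$truth$gene_id[fcs$truth$cluster == 1L]
    ann <- generate_annotation(fcs$fc$gene_id, sim$n_terms,
                               planted_term = list(term = "PLANTED",
                                                   genes = planted_genes),
                               term_size_range = sim$term_size_range,
                               seed = derive_seed(cfg$seed, 103L))
    emit(ann, "annotation.gmt", write_gmt)
    state$counts_sim <- cts
    state$fc_sim <- fcs
  })

  run_stage("call_degs", function() {
    ct_path <- cfg$inputs$contrast_table %||% path("contrast_table.tsv")
    contrasts <- read_contrast_table(ct_path)
    enriched <- call_enriched(contrasts, lfc_min = cfg$thresholds$lfc_min,
                              padj_max = cfg$thresholds$padj_max,
                              strict = cfg$thresholds$strict)
    emit(enriched, "enriched_sets.tsv", write_enriched_sets)
    design <- population_design()
    sectors <- dplyr::bind_rows(lapply(unique(design$group), function(grp) {
      pops <- design$population[design$group == grp]
      sub <- dplyr::filter(tibble::as_tibble(enriched), .data$population %in% pops)
      sub <- structure(sub, populations = pops,
                       class = c("enriched_sets", class(sub)))
      dplyr::mutate(classify_sectors(sub), group = grp)
    }))
    emit(sectors, "sectors.tsv", function(x, p) readr::write_tsv(x, p))
    state$enriched <- enriched
    state$sectors <- sectors
    if (!is.null(state$counts_sim)) {
      truth <- state$counts_sim$truth
      truth_pairs <- dplyr::bind_rows(lapply(which(!is.na(truth$label)), function(i) {
        tibble::tibble(gene_id = truth$gene_id[i],
                       population = strsplit(truth$label[i], "+", fixed = TRUE)[[1]])
      }))
      called <- tibble::as_tibble(enriched)[c("gene_id", "population")]
      tp <- nrow(dplyr::inner_join(called, truth_pairs, by = c("gene_id", "population")))
      manifest$stats$deg_sensitivity <<- if (nrow(truth_pairs)) tp / nrow(truth_pairs) else NA
      manifest$stats$deg_fdr <<- if (nrow(called)) 1 - tp / nrow(called) else 0
    }
  })

  run_stage("cluster", function() {
    fc_path <- cfg$inputs$fc_matrix %||% path("fc_matrix.tsv")
    fc <- read_matrix_tsv(fc_path)
    ens <- ensemble_config(n_iterations = cfg$ensemble$n_iterations,
                           k_min = cfg$ensemble$k_min,
                           subsample_min_frac = cfg$ensemble$subsample_min_frac,
                           kmeans_max_iter = cfg$ensemble$kmeans_max_iter,
                           kmeans_restarts = cfg$ensemble$kmeans_restarts,
                           seed = derive_seed(cfg$seed, 104L))
    res <- consensus_cluster(fc, ens, retain_frac = cfg$cluster$retain_frac,
                             n_trials = cfg$cluster$n_trials,
                             damping = cfg$cluster$damping)
    emit(res$assignment, "clusters.tsv", write_cluster_assignment)
    emit(res$graph, "consensus_graph.tsv", write_edge_list)
    emit(matrix_to_tibble(res$consensus$similarity), "similarity.tsv",
         write_matrix_tsv)
    state$clustering <- res
    if (!is.null(state$fc_sim)) {
      truth <- dplyr::rename(state$fc_sim$truth, true_cluster = "cluster")
      joined <- dplyr::inner_join(res$assignment, truth, by = "gene_id")
      manifest$stats$cluster_ari <<- mclust::adjustedRandIndex(
        joined$cluster, joined$true_cluster)
    }
  })

  run_stage("enrich", function() {
    gmt_path <- cfg$inputs$gmt %||% path("annotation.gmt")
    ann <- read_gmt(gmt_path)
    clusters <- state$clustering$assignment %||%
      read_cluster_assignment(path("clusters.tsv"))
    universe <- clusters$gene_id
    per_cluster <- dplyr::bind_rows(lapply(
      sort(unique(stats::na.omit(clusters$cluster))), function(cl) {
        q <- clusters$gene_id[!is.na(clusters$cluster) & clusters$cluster == cl]
        hits <- term_enrichment(q, universe, ann,
                                p_cutoff = cfg$enrich$p_cutoff,
                                min_overrep = cfg$enrich$min_overrep,
                                min_annotated = cfg$enrich$min_annotated)
        if (nrow(hits)) dplyr::mutate(hits, cluster = cl, .before = 1)
      }))
    emit(per_cluster, "enrichment.tsv", function(x, p) readr::write_tsv(x, p))
    state$enrichment <- per_cluster
  })

  run_stage("summarize", function() {
    clusters <- state$clustering$assignment %||%
      read_cluster_assignment(path("clusters.tsv"))
    cts <- state$counts_sim
    expr_path <- cfg$inputs$expression
    if (is.null(cts) && is.null(expr_path)) {
      abort_data("summarize needs simulated counts or inputs$expression")
    }
    if (!is.null(expr_path)) {
      expr <- read_matrix_tsv(expr_path)
    } else {
      m <- gene_matrix(cts$counts)
      norm <- sweep(m, 2, colSums(m) / mean(colSums(m)), "/")
      pops <- split(cts$samples$sample, cts$samples$population)
      expr <- matrix_to_tibble(
        vapply(pops, function(s) rowMeans(norm[, s, drop = FALSE]) + 1,
               numeric(nrow(m))))
    }
    epi <- c("epidermal-REV", "epidermal-KAN1", "epidermal-BFP-only")
    expr_epi <- expr[c("gene_id", intersect(epi, names(expr)))]
    summary <- summarize_cluster_expression(expr_epi, clusters,
                                            reference = "epidermal-BFP-only")
    emit(summary, "cluster_expression.tsv", function(x, p) readr::write_tsv(x, p))
    pref <- preferential_call(summary, fold_cutoff = cfg$thresholds$fold_cutoff)
    emit(pref, "preferential.tsv", function(x, p) readr::write_tsv(x, p))
    if (!is.null(state$sectors)) {
      sect <- dplyr::filter(state$sectors, .data$group == "epidermal")
      categories <- split(sect$gene_id, sect$sector)
      queries <- split(clusters$gene_id[!is.na(clusters$cluster)],
                      paste0("cluster", clusters$cluster[!is.na(clusters$cluster)]))
      if (length(categories)) {
        overlap <- overlap_percentages(queries, categories,
                                       background = clusters$gene_id)
        emit(overlap, "overlap.tsv", function(x, p) readr::write_tsv(x, p))
      }
    }
  })

  digests <- tools::md5sum(sort(unique(written)))
  manifest$files <- lapply(seq_along(digests), function(i) {
    list(file = basename(names(digests)[i]), md5 = unname(digests[i]))
  })
  tmp <- paste0(path("manifest.json"), ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  file.rename(tmp, path("manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
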
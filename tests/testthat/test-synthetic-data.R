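test_that("generators are pure functions of their arguments including seed", {
  nm <- noise_model(seed = 11)
  a <- generate_celltype_counts(population_design(), 40, 0.3, 2, nm)
  b <- generate_celltype_counts(population_design(), 40, 0.3, 2, nm)
  expect_identical(a, b)

  profs <- transient_profiles()
  fa <- generate_foldchange_matrix(profs, 10, nm)
  fb <- generate_foldchange_matrix(profs, 10, nm)
  expect_identical(fa, fb)

  ga <- generate_annotation(sprintf("g%03d", 1:50), 5, seed = 11)
  gb <- generate_annotation(sprintf("g%03d", 1:50), 5, seed = 11)
  expect_identical(ga, gb)
})

test_that("null effect leaves group-wise means equal up to sampling noise", {
  n_tested <- 0; n_kept <- 0
  for (s in 1:5) {
    sim <- generate_celltype_counts(population_design(n_replicates = 4), 200,
                                    frac_enriched = 0.3, effect_size = 0,
                                    noise = noise_model(seed = s))
    m <- as.matrix(sim$counts[-1])
    for (grp in c("epidermal", "subepidermal")) {
      cols <- sim$samples$sample[sim$samples$group == grp]
      pop <- factor(sim$samples$population[sim$samples$group == grp])
      p <- apply(m[, cols], 1, function(y) {
        stats::kruskal.test(y, pop)$p.value
      })
      n_tested <- n_tested + length(p)
      n_kept <- n_kept + sum(p > 0.001, na.rm = TRUE) + sum(is.na(p))
    }
  }
  expect_gte(n_kept / n_tested, 0.99)
})

test_that("planted genes carry the stated negative-binomial effect size", {
  ratios <- c()
  for (s in 1:3) {
    sim <- generate_celltype_counts(population_design(), 1000,
                                    frac_enriched = 0.2, effect_size = 2,
                                    noise = noise_model(dispersion = 0.1, seed = s))
    m <- as.matrix(sim$counts[-1])
    planted <- which(!is.na(sim$truth$label))
    r <- vapply(planted, function(i) {
      pops <- strsplit(sim$truth$label[i], "+", fixed = TRUE)[[1]]
      grp <- unique(sim$design$group[sim$design$population %in% pops])
      in_cols <- sim$samples$sample[sim$samples$population %in% pops]
      out_cols <- sim$samples$sample[sim$samples$group %in% grp &
                                       !sim$samples$population %in% pops]
      mean(m[i, in_cols]) / max(mean(m[i, out_cols]), 1e-9)
    }, numeric(1))
    ratios <- c(ratios, mean(r[is.finite(r)]))
  }
  expect_true(all(ratios > 2^1.5 & ratios < 2^2.5))
})

test_that("fold-change rows equal profile plus noise; zero noise is exact", {
  profs <- list(a = c(x = 2, y = -1), b = c(x = -0.5, y = 0.5))
  sim0 <- generate_foldchange_matrix(profs, 5, noise_model(fc_noise_sd = 0, seed = 1))
  m <- as.matrix(sim0$fc[-1])
  expect_equal(unname(m[sim0$truth$cluster == 1, ]),
               matrix(rep(c(2, -1), each = 5), 5, 2))
  expect_equal(unname(m[sim0$truth$cluster == 2, ]),
               matrix(rep(c(-0.5, 0.5), each = 5), 5, 2))

  # mean of each planted cluster converges to its profile
  sim <- generate_foldchange_matrix(profs, 400, noise_model(fc_noise_sd = 0.3, seed = 2))
  mm <- as.matrix(sim$fc[-1])
  for (cl in 1:2) {
    dev <- abs(colMeans(mm[sim$truth$cluster == cl, ]) - profs[[cl]])
    expect_lt(max(dev), 3 * 0.3 / sqrt(400))
  }
})

test_that("a plain 2-means oracle recovers two well-separated planted clusters", {
  profs <- list(up = c(a = 2, b = 2), down = c(a = -2, b = -2))
  sim <- generate_foldchange_matrix(profs, 50, noise_model(fc_noise_sd = 0.3, seed = 3))
  m <- as.matrix(sim$fc[-1])
  km <- withr::with_seed(1, stats::kmeans(m, centers = 2, nstart = 10))
  expect_equal(ari(km$cluster, sim$truth$cluster), 1)
})

test_that("the transient profile yields positive-early, negative-late rows", {
  profs <- list(transient = c(h6 = 1.7, h16 = -1.4),
                flat = c(h6 = 0, h16 = 0))
  sim <- generate_foldchange_matrix(profs, 60, noise_model(fc_noise_sd = 0.3, seed = 4))
  m <- as.matrix(sim$fc[-1])
  tr <- sim$truth$cluster == 1
  expect_gt(mean(m[tr, "h6"]), 0)
  expect_lt(mean(m[tr, "h16"]), 0)
})

test_that("generator input validation rejects inconsistent designs and profiles", {
  expect_error(population_design(c("a", "b"), c("g", "")), "without group")
  expect_error(population_design(c("a", "a"), c("g", "g")), "unique")
  expect_error(population_design(c("a", "b"), c("g", "g"), n_replicates = 1),
               "replicates")
  expect_error(
    generate_foldchange_matrix(list(a = c(x = 1), b = c(y = 1)), 5),
    "mismatched")
  expect_error(
    generate_foldchange_matrix(list(a = c(x = 1)), 5), ">= 2")
  expect_error(
    generate_annotation(c("g1", "g2"), 2,
                        planted_term = list(term = "T", genes = "zz")),
    "outside the universe")
})

test_that("contrast tables behave on hand-constructed counts", {
  design <- population_design(c("A", "B"), c("grp", "grp"), 2)
  # equal library sizes by construction (columns each sum to 500)
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           A.r1 = c(100, 400), A.r2 = c(100, 400),
                           B.r1 = c(400, 100), B.r2 = c(400, 100))
  ct <- contrasts_from_counts(counts, design)
  g1 <- ct[ct$gene_id == "g1" & ct$contrast == "A_vs_B", ]
  expect_equal(g1$log2fc, -2, tolerance = 0.02)  # pseudocount-negligible regime

  # identical replicate sets in both populations -> log2FC identically 0
  same <- tibble::tibble(gene_id = c("g1", "g2"),
                         A.r1 = c(10, 50), A.r2 = c(20, 60),
                         B.r1 = c(10, 50), B.r2 = c(20, 60))
  ct0 <- contrasts_from_counts(same, design)
  expect_true(all(ct0$log2fc == 0))
})

test_that("planted effects are detected with high power at n = 6 replicates", {
  for (s in 1:3) {
    sim <- generate_celltype_counts(population_design(n_replicates = 6), 300,
                                    frac_enriched = 0.2, effect_size = 3,
                                    noise = noise_model(dispersion = 0.05, seed = s))
    ct <- contrasts_from_counts(sim, sim$design)
    planted <- which(!is.na(sim$truth$label))
    hit <- vapply(planted, function(i) {
      pops <- strsplit(sim$truth$label[i], "+", fixed = TRUE)[[1]]
      rel <- ct[ct$gene_id == sim$truth$gene_id[i] &
                  grepl(paste0("^(", paste(pops, collapse = "|"), ")_vs_"),
                        ct$contrast), ]
      any(!is.na(rel$padj) & rel$padj < 0.05 & rel$log2fc > 1)
    }, logical(1))
    expect_gte(mean(hit), 0.9)
  }
})

test_that("annotation generator plants the exact term and writes valid GMT", {
  uni <- sprintf("g%04d", 1:1000)
  planted <- sample(uni, 20)
  ann <- generate_annotation(uni, 10, planted_term = list(term = "T1", genes = planted),
                             seed = 5)
  expect_equal(sort(ann$genes[[which(ann$term == "T1")]]), sort(planted))
  one <- generate_annotation(uni, 1, planted_term = list(term = "T1", genes = planted),
                             seed = 5)
  expect_equal(nrow(one), 1L)
  # planted 20-of-20 overlap in a 1000-gene universe is overwhelming evidence
  expect_lt(hyper_tail_oracle(20, 20, 1000, 20), 1e-10)
})
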
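test_that("the enrichment rule matches hand evaluation on the six-gene fixture", {
  en <- call_enriched(deg_fixture())
  expect_setequal(en$gene_id[en$population == "REV"],
                  deg_fixture_expected$enriched$REV)
  expect_length(en$gene_id[en$population == "KAN1"], 0)
  expect_length(en$gene_id[en$population == "BFP"], 0)
  # boundary gene gE excluded because the rule is strict ">"
  expect_false("gE" %in% en$gene_id)
  # with a non-strict flag the boundary gene is included
  en_ge <- call_enriched(deg_fixture(), strict = FALSE)
  expect_true("gE" %in% en_ge$gene_id[en_ge$population == "REV"])
})

test_that("single-contrast hits suffice and NA p-values never qualify", {
  ct <- tibble::tibble(
    gene_id = c("g1", "g2", "g2"),
    contrast = c("REV_vs_KAN1", "REV_vs_KAN1", "REV_vs_BFP"),
    log2fc = c(1.5, 3, 3),
    padj = c(0.01, NA, NaN))
  # only REV has both its within-group contrasts; the others are skipped
  expect_warning(en <- call_enriched(ct), "skipped")
  expect_equal(en$gene_id[en$population == "REV"], "g1")
})

test_that("mirrored orientations imply the same enrichment calls", {
  # gene enriched in BFP visible only through KAN1_vs_BFP with negative lfc
  ct <- tibble::tibble(
    gene_id = rep("g1", 3),
    contrast = c("REV_vs_KAN1", "REV_vs_BFP", "KAN1_vs_BFP"),
    log2fc = c(0, -1.6, -1.7),
    padj = c(1, 0.01, 0.01))
  en <- call_enriched(ct)
  expect_equal(en$gene_id[en$population == "BFP"], "g1")
})

test_that("tightening either threshold never adds a gene to any enriched set", {
  set.seed(42)
  pops <- c("REV", "KAN1", "BFP")
  prs <- t(utils::combn(pops, 2))
  ct <- tibble::tibble(
    gene_id = rep(sprintf("g%03d", 1:60), each = nrow(prs)),
    contrast = rep(paste0(prs[, 1], "_vs_", prs[, 2]), 60),
    log2fc = stats::rnorm(60 * nrow(prs), 0, 1.5),
    padj = stats::runif(60 * nrow(prs)))
  key <- function(en) paste(en$population, en$gene_id)
  base <- call_enriched(ct, lfc_min = 1, padj_max = 0.05)
  for (lfc in c(1.2, 1.5, 2)) {
    expect_true(all(key(call_enriched(ct, lfc_min = lfc)) %in% key(base)))
  }
  for (p in c(0.03, 0.01, 0.001)) {
    expect_true(all(key(call_enriched(ct, padj_max = p)) %in% key(base)))
  }
})

test_that("sector classification is exclusive, complete, and rejects triples", {
  mk <- function(df) structure(df, populations = c("REV", "KAN1", "BFP"),
                               class = c("enriched_sets", class(df)))
  # 10-gene fixture with known memberships
  en <- mk(tibble::tibble(
    population = c("REV", "REV", "REV", "KAN1", "KAN1", "BFP",
                   "REV", "BFP", "KAN1", "BFP", "REV", "KAN1"),
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6",
                "g7", "g7", "g8", "g8", "g9", "g9")))
  sec <- classify_sectors(en)
  expect_equal(nrow(sec), 9L)                      # every enriched gene once
  expect_equal(anyDuplicated(sec$gene_id), 0L)     # disjoint sectors
  tally <- table(sec$sector)
  expect_equal(unname(tally[c("REV-only", "KAN1-only", "BFP-only")]),
               c(3L, 2L, 1L), ignore_attr = TRUE)
  expect_equal(unname(tally[c("BFP+REV", "BFP+KAN1", "KAN1+REV")]),
               c(1L, 1L, 1L), ignore_attr = TRUE)

  triple <- mk(tibble::tibble(population = c("REV", "KAN1", "BFP"),
                              gene_id = rep("gX", 3)))
  expect_error(classify_sectors(triple), "gX")

  expect_equal(classify_sectors(call_enriched(deg_fixture()))$sector,
               deg_fixture_expected$sectors$sector)
})

test_that("cluster expression summaries recover planted ratios exactly", {
  expr <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                         REV = c(1, 1, 0.5, 0.5, 4, 4),
                         KAN1 = c(1, 1, 1, 1, 1, 1),
                         BFP = c(2, 2, 1, 1, 1, 1))
  clusters <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                             cluster = rep(1:3, each = 2))
  s <- summarize_cluster_expression(expr, clusters, reference = "BFP")
  expect_equal(s$BFP, rep(1, 3))
  expect_equal(s$REV, c(0.5, 0.5, 4), tolerance = 1e-12)
  expect_equal(s$KAN1, c(0.5, 1, 1), tolerance = 1e-12)

  # uniform expression -> all ones
  uni <- tibble::tibble(gene_id = c("a", "b"), REV = c(3, 5),
                        KAN1 = c(3, 5), BFP = c(3, 5))
  su <- summarize_cluster_expression(uni, tibble::tibble(gene_id = c("a", "b"),
                                                         cluster = c(1L, 1L)),
                                     reference = "BFP")
  expect_equal(unlist(su[-1]), c(REV = 1, KAN1 = 1, BFP = 1))

  # cluster with no member in the expression table is omitted with a warning
  expect_warning(
    summarize_cluster_expression(uni, tibble::tibble(gene_id = c("a", "b", "zz"),
                                                     cluster = c(1L, 1L, 2L)),
                                 reference = "BFP"),
    "omitted")
})

test_that("preferential calls agree with a brute-force predicate oracle", {
  expect_equal(preferential_call(tibble::tibble(cluster = 1, REV = 1,
                                                KAN1 = 1, BFP = 1))$preferred,
               "none")
  expect_equal(preferential_call(tibble::tibble(cluster = 1, REV = 1.6,
                                                KAN1 = 1, BFP = 1))$preferred,
               "REV")
  set.seed(7)
  for (i in 1:25) {
    s <- tibble::tibble(cluster = 1:4,
                        REV = stats::runif(4, 0.2, 3),
                        KAN1 = stats::runif(4, 0.2, 3),
                        BFP = stats::runif(4, 0.2, 3))
    got <- preferential_call(s, fold_cutoff = 1.5)
    oracle <- apply(as.matrix(s[-1]), 1, function(v) {
      hit <- sort(names(v)[v >= 1.5 * min(v)])
      if (length(hit)) paste(hit, collapse = "+") else "none"
    })
    expect_equal(got$preferred, unname(oracle))
  }
})
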
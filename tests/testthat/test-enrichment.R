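test_that("hypergeometric p-values match closed forms and degenerate cases", {
  uni <- sprintf("g%04d", 1:1000)
  ann <- list(T1 = uni[1:20])
  # query = the whole universe: no enrichment is possible (p = 1)
  res_all <- term_enrichment(uni, uni, ann, p_cutoff = 1.01, min_overrep = 0,
                             min_annotated = 0)
  expect_equal(res_all$p_value, 1)

  # 20-gene term fully inside a 20-gene query: p = 1 / choose(1000, 20)
  res <- term_enrichment(uni[1:20], uni, ann, min_overrep = 1, min_annotated = 1)
  expect_equal(log(res$p_value), -lchoose(1000, 20), tolerance = 1e-10)
})

test_that("the reporting filters drop strong but small overlaps", {
  uni <- sprintf("g%03d", 1:500)
  ann <- list(small = uni[1:4], big = uni[5:40])
  res <- term_enrichment(uni[1:24], uni, ann)
  # 'small' is strongly enriched (p ~ 8e-6) but has only 4 over-represented
  # genes -> removed by the min-overrep filter
  expect_false("small" %in% res$term)
  all_terms <- attr(res, "all_terms")
  expect_lt(all_terms$p_value[all_terms$term == "small"], 1e-4)
})

test_that("implementation agrees with the exact enumeration oracle on small universes", {
  for (N in c(6, 13, 21, 30)) {
    uni <- sprintf("u%02d", 1:N)
    for (K in c(1, floor(N / 3), N - 1)) {
      for (n in c(1, floor(N / 2), N)) {
        ann <- list(T = uni[seq_len(K)])
        res <- attr(term_enrichment(uni[seq_len(n)], uni, ann,
                                    p_cutoff = 1.01, min_overrep = 0,
                                    min_annotated = 0), "all_terms")
        k <- length(intersect(uni[seq_len(K)], uni[seq_len(n)]))
        expect_equal(res$p_value, hyper_tail_oracle(k, K, N, n),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("a planted term ranks first whenever it passes the filters", {
  uni <- sprintf("g%04d", 1:800)
  for (s in 1:3) {
    planted <- withr::with_seed(s + 777, sample(uni, 25))
    ann <- generate_annotation(uni, 15,
                               planted_term = list(term = "PL", genes = planted),
                               seed = s)
    query <- c(planted[1:15], withr::with_seed(s + 100, sample(setdiff(uni, planted), 10)))
    res <- term_enrichment(query, uni, ann)
    expect_equal(res$term[1], "PL")
  }
})

test_that("input validation: empty inputs and zero-overlap terms", {
  uni <- sprintf("g%02d", 1:20)
  expect_error(term_enrichment(character(), uni, list(T = uni[1:5])), "non-empty")
  expect_error(term_enrichment(c("zzz"), uni, list(T = uni[1:5])), "outside")
  res <- term_enrichment(uni[1:10], uni, list(gone = c("x1", "x2")),
                         p_cutoff = 1.01, min_overrep = 0, min_annotated = 0)
  expect_equal(nrow(res), 0L)  # zero-universe-overlap term skipped
})

test_that("overlap percentages are exact and rounded only at presentation", {
  qs <- list(q1 = sprintf("g%02d", 1:10))
  cats <- list(A = sprintf("g%02d", 1:6), B = sprintf("g%02d", 7:12))
  ov <- overlap_percentages(qs, cats)
  expect_equal(ov$n, c(6L, 4L))
  expect_equal(ov$percent, c(60, 40))
  expect_equal(sum(ov$percent), 100)

  # disjoint query -> zeros
  ov0 <- overlap_percentages(list(q = c("zz1", "zz2")), cats)
  expect_equal(ov0$n, c(0L, 0L))
  expect_error(overlap_percentages(qs, list(A = c("g01"), B = c("g01", "g02"))),
               "disjoint")

  # three-ish-way table emulating auxin-responsive sets vs regulation classes
  cats2 <- list(celltype_specific = sprintf("g%02d", 1:30),
                rev_kan1_regulated = sprintf("g%02d", 31:60),
                unclassified = sprintf("g%02d", 61:99))
  qs2 <- list(auxin_up = sprintf("g%02d", c(1:10, 31:35, 61:63)),
              auxin_down = sprintf("g%02d", c(11:13, 36:50)))
  ov2 <- overlap_percentages(qs2, cats2, background = sprintf("g%02d", 1:99))
  up <- ov2[ov2$query == "auxin_up", ]
  expect_equal(up$n, c(10L, 5L, 3L))
  expect_equal(up$percent, 100 * c(10, 5, 3) / 18)
  allrow <- ov2[ov2$query == "all", ]
  expect_equal(allrow$n, c(30L, 30L, 39L))
  wide <- format_overlap_table(ov2)
  expect_equal(wide$celltype_specific[wide$query == "auxin_up"],
               round(1000 / 18))
})

test_that("co-regulation fractions partition the shared DEG set", {
  up_both <- tibble::tibble(regulator = rep(c("REV", "KAN1"), each = 2),
                            direction = "up", gene_id = rep(c("g1", "g2"), 2))
  r <- coregulation_table(up_both)
  expect_equal(r$co_induced, 1)
  expect_equal(r$n_shared, 2L)

  opp <- tibble::tibble(regulator = c("A", "A", "B", "B"),
                        direction = c("up", "up", "down", "down"),
                        gene_id = c("g1", "g2", "g1", "g2"))
  expect_equal(coregulation_table(opp)$opposite, 1)

  # planted 50/30/20 split among 100 shared genes
  ids <- sprintf("g%03d", 1:100)
  a_dir <- c(rep("up", 50), rep("down", 30), rep("up", 10), rep("down", 10))
  b_dir <- c(rep("up", 50), rep("down", 30), rep("down", 10), rep("up", 10))
  mix <- tibble::tibble(regulator = rep(c("A", "B"), each = 100),
                        direction = c(a_dir, b_dir), gene_id = rep(ids, 2))
  r3 <- coregulation_table(mix)
  expect_equal(c(r3$co_induced, r3$co_repressed, r3$opposite), c(0.5, 0.3, 0.2))
  expect_equal(r3$co_induced + r3$co_repressed + r3$opposite, 1)

  bad <- tibble::tibble(regulator = c("A", "A", "B"),
                        direction = c("up", "down", "up"),
                        gene_id = c("g1", "g1", "g1"))
  expect_error(coregulation_table(bad), "both up- and down")
})
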
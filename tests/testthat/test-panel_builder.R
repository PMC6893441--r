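test_that("replicate averaging takes per-gene means over tables where present", {
  r1 <- binding_score_table("r1", "human", "grp", c("A", "B"), c(10, 2))
  r2 <- binding_score_table("r2", "human", "grp", c("A", "B"), c(6, 4))
  avg <- average_replicates(list(r1, r2))
  expect_length(avg, 1)
  sc <- setNames(avg[[1]]$entries$score, avg[[1]]$entries$gene)
  expect_equal(unname(sc[c("A", "B")]), c(8, 3))

  # present-only averaging: gene in one of two replicates keeps its score
  r3 <- binding_score_table("r3", "human", "grp", c("A", "C"), c(2, 6))
  sc2 <- with(average_replicates(list(r1, r3))[[1]],
              setNames(entries$score, entries$gene))
  expect_equal(unname(sc2[c("A", "B", "C")]), c(6, 2, 6))

  # singleton groups pass through untouched
  single <- average_replicates(list(r1))
  expect_identical(single[[1]], r1)

  # species may not mix within a group
  rm <- binding_score_table("rm", "mouse", "grp", "A", 1)
  expect_error(average_replicates(list(r1, rm)), "species")
})

test_that("top-K selection is deterministic with lexicographic tie-breaks", {
  tbl <- binding_score_table("d", "human", "d",
                             c("C", "B", "A"), c(4, 5, 5))
  expect_identical(top_k_genes(tbl, 2)$symbols, c("A", "B"))
  expect_identical(top_k_genes(tbl, 10)$symbols, c("A", "B", "C"))

  # row order of the input table must not matter
  tbl2 <- binding_score_table("d", "human", "d",
                              c("A", "C", "B"), c(5, 4, 5))
  expect_identical(top_k_genes(tbl2, 2)$symbols,
                   top_k_genes(tbl, 2)$symbols)
})

test_that("multi-list membership keeps genes seen in at least two lists", {
  lists <- list(gene_list(c("A", "B", "C"), "l1"),
                gene_list(c("B", "C", "D"), "l2"),
                gene_list(c("C", "E"), "l3"))
  expr <- toy_expr(c("A", "B", "C", "D", "E"), 6)
  p <- build_panel(lists, species = rep("human", 3),
                   orthologs = NULL, expr = expr,
                   canonical = character(0))
  expect_identical(p$symbols, c("B", "C"))
  expect_equal(p$counts$n_multi_list, 2)
  expect_equal(p$counts$n_canonical_added, 0)
  expect_equal(p$counts$n_final, 2)
})

test_that("ortholog mapping lets a mouse list corroborate a human list", {
  lists <- list(gene_list(c("MMABCA1", "MUSGX"), "mouse_ds"),
                gene_list(c("ABCA1", "APOE"), "human_ds"))
  om <- data.frame(source_symbol = "MMABCA1", human_symbol = "ABCA1")
  expr <- toy_expr(c("ABCA1", "APOE"), 5)
  p <- build_panel(lists, species = c("mouse", "human"),
                   orthologs = om, expr = expr, canonical = character(0))
  expect_identical(p$symbols, "ABCA1")
  # MUSGX was only in one list: recorded nowhere near the ortholog drops
  expect_equal(p$counts$n_dropped_no_ortholog, 0)
})

test_that("unmapped multi-list symbols are counted as ortholog drops", {
  lists <- list(gene_list(c("MUSGX", "MMAPOE"), "m1"),
                gene_list(c("MUSGX", "MMAPOE"), "m2"))
  om <- data.frame(source_symbol = "MMAPOE", human_symbol = "APOE")
  expr <- toy_expr("APOE", 5)
  p <- build_panel(lists, species = c("mouse", "mouse"),
                   orthologs = om, expr = expr, canonical = character(0))
  expect_identical(p$symbols, "APOE")
  expect_equal(p$counts$n_dropped_no_ortholog, 1)
  expect_equal(p$counts$n_multi_list, 2)
})

test_that("expression-presence filter drops absent or mostly-missing genes", {
  lists <- list(gene_list(c("A", "B", "C"), "l1"),
                gene_list(c("A", "B", "C"), "l2"))
  expr <- toy_expr(c("A", "B"), 4)
  expr["B", 1:3] <- NA   # present in 25% of samples < default 50%
  p <- build_panel(lists, species = rep("human", 2),
                   orthologs = NULL, expr = expr, canonical = character(0))
  expect_identical(p$symbols, "A")
  expect_equal(p$counts$n_dropped_not_expressed, 2)  # B (missing) + C (absent)
})

test_that("canonical targets bypass filters and are flagged when unmeasured", {
  lists <- list(gene_list(c("A", "B"), "l1"), gene_list(c("A", "B"), "l2"))
  expr <- toy_expr(c("A", "B"), 5)
  p <- build_panel(lists, species = rep("human", 2), orthologs = NULL,
                   expr = expr,
                   canonical = gene_list(c("B", "ZZZ"), "canon"))
  expect_identical(p$symbols, c("A", "B", "ZZZ"))
  expect_equal(p$counts$n_canonical_added, 1)          # B already present
  prov <- p$provenance
  expect_false(prov$in_expression[prov$symbol == "ZZZ"])
  expect_identical(prov$source[prov$symbol == "B"], "both")

  # empty canonical list leaves the filtered panel unchanged
  p0 <- build_panel(lists, species = rep("human", 2), orthologs = NULL,
                    expr = expr, canonical = character(0))
  expect_identical(p0$symbols, c("A", "B"))
})

test_that("panels are deterministic under input permutation and monotone in membership", {
  set.seed(42)
  pool <- sprintf("G%02d", 1:30)
  for (case in 1:15) {
    lists <- lapply(1:4, function(i) {
      gene_list(sample(pool, sample(5:15, 1)), paste0("l", i))
    })
    expr <- toy_expr(pool, 8, seed = case)
    args <- list(species = rep("human", 4), orthologs = NULL, expr = expr,
                 canonical = gene_list(sample(pool, 3), "canon"))
    p1 <- do.call(build_panel, c(list(lists), args))
    # permute list order and within-list symbol order
    lists_perm <- lapply(rev(lists), function(gl) {
      gene_list(sample(gl$symbols), gl$label)
    })
    p2 <- do.call(build_panel, c(list(lists_perm), args))
    expect_identical(p1$symbols, p2$symbols)

    # bookkeeping identity holds on every run
    expect_equal(p1$counts$n_final,
                 p1$counts$n_after_filters + p1$counts$n_canonical_added)
    expect_equal(p1$counts$n_multi_list - p1$counts$n_dropped_no_ortholog -
                   p1$counts$n_dropped_not_expressed,
                 p1$counts$n_after_filters)

    # raising the membership requirement never grows the pre-union panel
    sizes <- vapply(1:4, function(k) {
      cfgk <- panel_config(min_list_membership = k)
      do.call(build_panel, c(list(lists), args,
                             list(cfg = cfgk)))$counts$n_after_filters
    }, 0L)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("an empty list collection is rejected", {
  expect_error(build_panel(list(), character(0), NULL,
                           toy_expr("A", 3), character(0)),
               "no binding lists")
})
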
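test_that("the significance filter honors its boundary semantics", {
  tbl <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    chemical = "x", concentration_nM = 1, duration = "24h",
    log2fc = c(0.75, 0.74, -1.2, 2),
    padj = c(0.099, 1e-10, 0.05, 0.1)
  )
  sig <- filter_degs(tbl)
  expect_equal(sig$gene_id, c("a", "c")) # b below |lfc| cut, d at padj boundary
  expect_equal(sig$direction, c("up", "down"))
  expect_equal(attr(sig, "n_untested"), 0)

  tbl$padj[2] <- NA # missing adjusted p is never significant
  sig <- filter_degs(tbl)
  expect_equal(attr(sig, "n_untested"), 1)

  tbl$padj[1] <- 1.5
  expect_error(filter_degs(tbl), "\\[0, 1\\]")
})

test_that("the filter matches a brute-force row scan and is monotone", {
  set.seed(37)
  for (i in 1:50) {
    n <- 200
    tbl <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:n),
      chemical = "x", concentration_nM = 1, duration = "24h",
      log2fc = rnorm(n, 0, 1),
      padj = ifelse(runif(n) < 0.05, NA, runif(n))
    )
    sig <- filter_degs(tbl)
    expect_equal(sig$gene_id, oracle_filter(tbl))
    # relaxing either threshold never shrinks the set
    relaxed_lfc <- filter_degs(tbl, lfc_cut = 0.5)
    relaxed_p <- filter_degs(tbl, padj_cut = 0.2)
    expect_true(all(sig$gene_id %in% relaxed_lfc$gene_id))
    expect_true(all(sig$gene_id %in% relaxed_p$gene_id))
  }
})

test_that("count deduplication policies differ exactly by repeat genes", {
  base <- tibble::tibble(
    chemical = "x", duration = "24h",
    gene_id = c("g1", "g1", "g2"),
    concentration_nM = c(1, 10, 1),
    log2fc = c(1, 1, -1), padj = 0.01
  )
  sig <- filter_degs(base)
  sum_counts <- count_by_condition(sig, "sum")
  uni_counts <- count_by_condition(sig, "unique")
  expect_equal(sum_counts$per_duration$n_total, 3)
  expect_equal(uni_counts$per_duration$n_total, 2)
  expect_equal(uni_counts$per_duration$n_variably_regulated, 0)

  # opposite signs at two concentrations: variably regulated once
  flip <- base
  flip$log2fc <- c(1, -1, -1)
  sig <- filter_degs(flip)
  uni <- count_by_condition(sig, "unique")
  expect_equal(uni$per_duration$n_total, 2)
  expect_equal(uni$per_duration$n_variably_regulated, 1)
  expect_equal(count_by_condition(sig, "sum")$per_duration$n_total, 3)
  expect_error(count_by_condition(sig, "bogus"))
})

test_that("unique totals never exceed sum totals on random tables", {
  set.seed(43)
  for (i in 1:30) {
    sig <- tibble::tibble(
      gene_id = sample(sprintf("g%02d", 1:30), 60, replace = TRUE),
      chemical = "x", duration = "24h",
      concentration_nM = sample(c(1, 10, 100), 60, replace = TRUE),
      log2fc = sample(c(-1, 1), 60, replace = TRUE),
      padj = 0.01
    ) |> dplyr::distinct(gene_id, concentration_nM, .keep_all = TRUE)
    sig$direction <- ifelse(sig$log2fc > 0, "up", "down")
    s <- count_by_condition(sig, "sum")$per_duration$n_total
    u <- count_by_condition(sig, "unique")$per_duration$n_total
    expect_lte(u, s)
    if (!anyDuplicated(sig$gene_id)) expect_equal(u, s)
  }
})

test_that("Venn regions are exact on the enumerable example", {
  res <- overlap_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = "c"))
  get <- function(region) {
    row <- res[res$region == region, ]
    if (nrow(row) == 0) 0L else row$n
  }
  expect_equal(get("A"), 1) # {a}
  expect_equal(get("A&B"), 1) # {b}
  expect_equal(get("A&B&C"), 1) # {c}
  expect_equal(get("B"), 1) # {d}
  expect_equal(sum(res$n), 4)
  expect_equal(res$genes[res$region == "A&B&C"][[1]], "c")

  same <- overlap_sets(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(same$region, "X&Y")
  expect_equal(same$n, 2)

  expect_error(overlap_sets(list(c("a"), c("b"))), "names")
  expect_error(overlap_sets(list(A = "a", A = "b")), "unique")
  expect_error(overlap_sets(list(A = "a")), "two")
})

test_that("Venn regions are disjoint and sum to the union on random sets", {
  set.seed(47)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    sets <- purrr::map(seq_len(k), function(j) {
      sample(sprintf("g%02d", 1:25), sample(3:15, 1))
    })
    names(sets) <- LETTERS[seq_len(k)]
    res <- overlap_sets(sets)
    oracle <- oracle_venn(sets)
    expect_equal(sum(res$n), length(unique(unlist(sets))))
    expect_setequal(res$region, names(oracle))
    expect_equal(res$n, unname(as.integer(oracle[res$region])))
    # disjoint: no gene appears in two regions
    all_genes <- unlist(res$genes)
    expect_false(anyDuplicated(all_genes) > 0)
  }
})

test_that("category annotation left-joins and counts per policy", {
  sig <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"),
    chemical = "x", concentration_nM = c(1, 10, 1), duration = "24h",
    log2fc = 1, padj = 0.01, direction = "up"
  )
  empty_map <- tibble::tibble(gene_id = character(), category = character())
  res <- annotate_categories(sig, empty_map)
  expect_true(all(res$records$category == "unassigned"))

  map <- tibble::tibble(gene_id = "g1", category = "cardiovascular")
  expect_equal(
    annotate_categories(sig, map, "sum")$counts$n[
      annotate_categories(sig, map, "sum")$counts$category == "cardiovascular"
    ], 2
  )
  expect_equal(
    annotate_categories(sig, map, "unique")$counts$n[
      annotate_categories(sig, map, "unique")$counts$category == "cardiovascular"
    ], 1
  )
  bad <- tibble::tibble(gene = "g1", label = "x")
  expect_error(annotate_categories(sig, bad), "malformed")
})
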
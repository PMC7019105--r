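test_that("cleaning drops low-total genes and cells at the thresholds", {
  # gene 2 totals 9 (dropped); cell 3 totals 9999 over kept genes (dropped)
  counts <- rbind(
    g_keep = c(6000, 5000, 6000),
    g_low  = c(4, 3, 2),
    g_big  = c(5000, 6000, 3997)
  )
  cm <- count_matrix(counts, cell_ids = c("c1", "c2", "c3"))
  out <- clean_counts(cm)
  expect_identical(out$gene_ids, c("g_keep", "g_big"))
  expect_identical(out$cell_ids, c("c1", "c2"))
  expect_identical(attr(out, "kept_genes"), c(1L, 3L))
  expect_identical(attr(out, "kept_cells"), c(1L, 2L))
})

test_that("matrices already above both thresholds pass through unchanged", {
  cm <- count_matrix(matrix(6000, 3, 2))
  out <- clean_counts(cm)
  expect_identical(out$counts, cm$counts)
})

test_that("spike-in rows are exempt from the gene filter by default", {
  counts <- rbind(c(9000, 9000), c(2, 1), c(3, 1))
  cm <- count_matrix(counts, gene_ids = c("g1", "g2", "ERCC-1"),
                     is_spikein = c(FALSE, FALSE, TRUE))
  out <- clean_counts(cm, min_cell_total = 100)
  expect_identical(out$gene_ids, c("g1", "ERCC-1"))
  strict <- clean_counts(cm, min_cell_total = 100, exempt_spikeins = FALSE)
  expect_identical(strict$gene_ids, "g1")
})

test_that("cleaning is single-pass: dropping cells can strand gene totals", {
  # g2's total is >= 10 only thanks to the low-count cell that the cell
  # filter removes; one pass keeps g2, a second pass (iterate) drops it
  counts <- rbind(g1 = c(200, 200, 5), g2 = c(4, 4, 9))
  cm <- count_matrix(counts)
  once <- clean_counts(cm, min_gene_total = 10, min_cell_total = 100)
  expect_identical(once$gene_ids, c("g1", "g2"))
  expect_equal(ncol(once$counts), 2)
  expect_lt(sum(once$counts["g2", ]), 10)  # stranded below threshold
  fixed <- clean_counts(cm, min_gene_total = 10, min_cell_total = 100,
                        iterate = TRUE)
  expect_identical(fixed$gene_ids, "g1")
})

test_that("cleaning errors when everything is removed", {
  cm <- count_matrix(matrix(1, 2, 2))
  expect_error(clean_counts(cm), "every gene|every cell")
})

test_that("FPKM matches its closed form and scaling symmetries", {
  cm <- count_matrix(matrix(c(10, 999990), 2, 1),
                     gene_ids = c("a", "b"), gene_lengths = c(2000, 1000))
  expect_equal(compute_fpkm(cm)["a", 1], 5.0)

  # zero counts give zero FPKM
  cm0 <- count_matrix(matrix(c(0, 100), 2, 1), gene_lengths = c(500, 500))
  expect_equal(compute_fpkm(cm0)[1, 1], 0)

  # uniform 2x scaling of a column leaves its FPKM unchanged
  m <- matrix(c(3, 7, 10, 6, 14, 20), 3)
  cm1 <- count_matrix(m[, 1, drop = FALSE], gene_lengths = c(100, 200, 300))
  cm2 <- count_matrix(m[, 2, drop = FALSE], gene_lengths = c(100, 200, 300))
  expect_equal(compute_fpkm(cm1), compute_fpkm(cm2), ignore_attr = TRUE)

  # scaling one gene's count by k with the column total held fixed scales
  # its FPKM by k
  a <- count_matrix(matrix(c(10, 90), 2, 1), gene_lengths = c(100, 100))
  b <- count_matrix(matrix(c(30, 70), 2, 1), gene_lengths = c(100, 100))
  expect_equal(compute_fpkm(b)[1, 1], 3 * compute_fpkm(a)[1, 1])

  expect_error(compute_fpkm(count_matrix(matrix(1, 1, 1))), "lengths")
  czero <- count_matrix(matrix(c(1, 0), 1), cell_ids = c("ok", "empty"),
                        gene_lengths = 100)
  expect_error(compute_fpkm(czero), "empty")
})
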
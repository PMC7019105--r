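test_that("template parameter estimation matches its moment definitions", {
  cm <- count_matrix(matrix(c(5, 10, 5, 10), 2))
  tp <- estimate_template_params(cm)
  expect_equal(tp$cell_factor, c(1, 1), ignore_attr = TRUE)
  expect_equal(tp$gene_dispersion, c(0, 0), ignore_attr = TRUE)

  cm2 <- count_matrix(matrix(c(40, 60, 120, 180), 2))
  expect_equal(estimate_template_params(cm2)$cell_factor, c(0.5, 1.5),
               ignore_attr = TRUE)

  expect_error(estimate_template_params(count_matrix(matrix(1:2, 2))),
               "two cells")
})

test_that("dispersion recovers from NB draws at 500 cells", {
  n_genes <- 200
  sim <- simulate_counts(n_cells_per_group = 250,
                         gene_mean = rep(50, n_genes),
                         gene_dispersion = rep(0.2, n_genes),
                         cell_factor = rep(1, 500),
                         fold_change = 1, n_de = 0, seed = 21)
  tp <- estimate_template_params(sim$counts)
  ok <- abs(tp$gene_dispersion - 0.2) / 0.2 <= 0.2
  expect_gte(mean(ok), 0.9)
})

test_that("the simulator is deterministic and validates its arguments", {
  a <- simulate_counts(n_cells_per_group = 5, n_genes = 50, seed = 3)
  b <- simulate_counts(n_cells_per_group = 5, n_genes = 50, seed = 3)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$de_flags, b$truth$de_flags)
  c <- simulate_counts(n_cells_per_group = 5, n_genes = 50, seed = 4)
  expect_false(identical(a$counts$counts, c$counts$counts))

  expect_error(simulate_counts(fold_change = 0.5), "fold change")
  expect_error(simulate_counts(n_cells_per_group = 1), "two cells")
})

test_that("fold-change injection hits only the flagged genes", {
  sim <- simulate_counts(n_cells_per_group = 2000, n_genes = 300,
                         gene_mean = rep(20, 300),
                         gene_dispersion = rep(0.3, 300),
                         cell_factor = rep(1, 4000),
                         fold_change = 2, n_de = 60, seed = 8)
  g2 <- sim$truth$group_label == "group2"
  m1 <- rowMeans(sim$counts$counts[, !g2])
  m2 <- rowMeans(sim$counts$counts[, g2])
  ratio_de <- m2[sim$truth$de_flags] / m1[sim$truth$de_flags]
  expect_true(all(ratio_de >= 1.8 & ratio_de <= 2.2))
  ratio_null <- m2[!sim$truth$de_flags] / m1[!sim$truth$de_flags]
  expect_true(all(abs(ratio_null - 1) < 0.2))
})

test_that("null simulations are exchangeable between the two groups", {
  sim <- simulate_counts(n_cells_per_group = 100, n_genes = 400,
                         fold_change = 1, n_de = 0, seed = 17)
  g2 <- sim$truth$group_label == "group2"
  p <- apply(sim$counts$counts, 1, function(v) {
    if (stats::sd(v) == 0) return(1)
    stats::wilcox.test(v[!g2], v[g2], exact = FALSE)$p.value
  })
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("zero dispersion reduces to Poisson (variance ~ mean)", {
  sim <- simulate_counts(n_cells_per_group = 1000, n_genes = 200,
                         gene_mean = rep(30, 200),
                         gene_dispersion = rep(0, 200),
                         cell_factor = rep(1, 2000),
                         fold_change = 1, n_de = 0, seed = 12)
  vm <- apply(sim$counts$counts, 1, stats::var) /
    rowMeans(sim$counts$counts)
  expect_true(all(abs(vm - 1) < 0.1))
})

test_that("simulated moments match mean m and variance m + phi m^2", {
  phi <- 0.4
  sim <- simulate_counts(n_cells_per_group = 1000, n_genes = 150,
                         gene_mean = rep(40, 150),
                         gene_dispersion = rep(phi, 150),
                         cell_factor = rep(1, 2000),
                         fold_change = 1, n_de = 0, seed = 31)
  m <- rowMeans(sim$counts$counts)
  v <- apply(sim$counts$counts, 1, stats::var)
  se_mean <- sqrt((40 + phi * 40^2) / 2000)
  expect_gte(mean(abs(m - 40) <= 3 * se_mean), 0.99)  # ~3-sigma coverage
  expect_true(all(abs(m - 40) <= 5 * se_mean))
  # variance of the sample variance for NB, normal approximation envelope
  expect_true(mean(abs(v - (40 + phi * 40^2)) / (40 + phi * 40^2) < 0.2)
              > 0.95)
})

test_that("cell factors round-trip through template estimation", {
  withr::with_seed(5, {
    f <- stats::rlnorm(300, 0, 0.5)
    mu <- stats::rlnorm(2000, 2, 1)
  })
  sim <- simulate_counts(n_cells_per_group = 150,
                         gene_mean = mu,
                         gene_dispersion = rep(0.4, 2000),
                         cell_factor = f, fold_change = 1, n_de = 0,
                         seed = 6)
  tp <- estimate_template_params(sim$counts)
  expect_gt(stats::cor(tp$cell_factor, f), 0.99)
})

test_that("spike-in simulation matches the Poisson-Gamma branch", {
  ref <- synthetic_spike_reference(n = 12, top = 400, step = 1.5)
  noiseless <- simulate_spikeins(ref, n_cells = 1000,
                                 capture_efficiency = 1, noise_theta = 0,
                                 seed = 9)
  emp <- rowMeans(noiseless$counts$counts)
  expect_true(all(abs(emp - noiseless$spike_mean) / noiseless$spike_mean
                  <= 0.05))
  expect_true(all(noiseless$counts$is_spikein))

  noisy <- simulate_spikeins(ref, n_cells = 1000, capture_efficiency = 1,
                             noise_theta = 0.5, seed = 9)
  cv2 <- function(x) stats::var(x) / mean(x)^2
  expect_gt(cv2(colSums(noisy$counts$counts)),
            cv2(colSums(noiseless$counts$counts)))

  expect_error(simulate_spikeins(ref[0, ], 10), "empty")
})

test_that("labels attach from truth, idempotently, with length checks", {
  sim <- simulate_counts(n_cells_per_group = 20, n_genes = 30, seed = 2)
  cm <- sim$counts
  cm$condition <- NULL
  lab <- attach_labels(cm, sim$truth)
  expect_identical(table(lab$condition),
                   table(c(rep("group1", 20), rep("group2", 20))))
  expect_identical(attach_labels(lab, sim$truth)$condition, lab$condition)

  small <- subset_counts(cm, cells = 1:10)
  expect_error(attach_labels(small, sim$truth), "40 labels.*10 cells")
})
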
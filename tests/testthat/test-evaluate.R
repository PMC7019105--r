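test_that("kappa matches hand-computed values and its symmetries", {
  expect_equal(cohens_kappa(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(cohens_kappa(matrix(c(9, 81, 1, 9), 2)), 0)   # p_o = p_e
  expect_equal(cohens_kappa(matrix(c(40, 20, 10, 30), 2)), 0.4)

  expect_error(cohens_kappa(matrix(0, 2, 2)), "empty")
  expect_error(cohens_kappa(matrix(1:6, 2)), "square")

  # kappa = 1 iff the matrix is diagonal
  withr::with_seed(3, m <- matrix(rpois(16, 5) + 1, 4))
  expect_lt(cohens_kappa(m), 1)
  expect_equal(cohens_kappa(diag(c(3, 9, 1, 7))), 1)

  # invariant under simultaneous row/column permutation
  p <- c(3, 1, 4, 2)
  expect_equal(cohens_kappa(m[p, p]), cohens_kappa(m))
})

test_that("repeated KNN separates clear clusters and nulls out noise", {
  withr::with_seed(5, {
    a <- matrix(rnorm(60, 0, 0.01), ncol = 2)
    b <- matrix(rnorm(60, 5, 0.01), ncol = 2)
  })
  vals <- rbind(a, b)
  labels <- rep(c("A", "B"), each = 30)
  kap <- knn_classify_repeated(vals, labels, n_repeats = 20, seed = 2)
  expect_equal(kap, rep(1, 20))

  perm <- withr::with_seed(9, sample(labels))
  kap0 <- knn_classify_repeated(vals, perm, n_repeats = 100, seed = 2)
  expect_lt(abs(mean(kap0)), 0.1)

  expect_error(knn_classify_repeated(vals, rep("A", 60)), "two conditions")
  expect_error(
    knn_classify_repeated(vals, c(rep("A", 57), rep("B", 3)), k = 5),
    "fewer than k")

  expect_identical(knn_classify_repeated(vals, labels, n_repeats = 5,
                                         seed = 7),
                   knn_classify_repeated(vals, labels, n_repeats = 5,
                                         seed = 7))
  # the protocol defaults to 100 random splits
  expect_equal(formals(knn_classify_repeated)$n_repeats, 100)
})

test_that("PCA embedding matches an eigendecomposition oracle", {
  withr::with_seed(6, v <- matrix(rnorm(200), 20, 10))
  scores <- pca_embed(v, n_components = 9)

  obs <- scale(t(v), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(obs))
  oracle <- obs %*% eig$vectors[, 1:9]
  for (k in 1:9) {
    expect_equal(abs(scores[, k]), abs(oracle[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # rank-1 input: first component owns essentially all variance
  r1 <- outer(1:15, rnorm(8))
  s1 <- pca_embed(r1, n_components = 3)
  sd1 <- attr(s1, "sdev")
  expect_gte(sd1[1]^2 / sum(sd1^2), 0.9999)

  # rotating the gene space preserves pairwise score distances
  withr::with_seed(8, q <- qr.Q(qr(matrix(rnorm(400), 20))))
  rot <- pca_embed(q %*% v, n_components = 9)
  expect_equal(as.matrix(stats::dist(rot)), as.matrix(stats::dist(scores)),
               tolerance = 1e-8)

  expect_error(pca_embed(matrix(3, 4, 4)), "constant")
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  withr::with_seed(10, p <- runif(50))
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # the monotonicity (cumulative-minimum) enforcement is idempotent: the
  # sorted adjusted values already satisfy it
  s <- sort(adj)
  expect_equal(rev(cummin(rev(s))), s)
  expect_true(all(diff(adj[order(p)]) >= 0))  # rank-monotone
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DE screening is calibrated under the null", {
  sim <- simulate_counts(n_cells_per_group = 40, n_genes = 2000,
                         fold_change = 1, n_de = 0, seed = 44)
  nm <- normalize_simple(sim$counts)
  scr <- de_screen(nm, sim$counts$condition)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lte(scr$n_significant / 2000, 0.05 + 2 * se)
  expect_error(de_screen(nm, rep(c("a", "b", "c"), length.out = 80)),
               "pairwise")
})

test_that("the NB Wald screen flags an obvious fold change", {
  sim <- simulate_counts(n_cells_per_group = 25, n_genes = 60,
                         gene_mean = rep(30, 60),
                         gene_dispersion = rep(0.2, 60),
                         cell_factor = rep(1, 50),
                         fold_change = 6, n_de = 10, seed = 51)
  scr <- de_screen(sim$counts$counts, sim$counts$condition,
                   test = "nb_wald")
  sens <- mean(scr$significant[sim$truth$de_flags])
  expect_gte(sens, 0.8)
})

test_that("flagged genes are mostly true positives on strong signal", {
  sim <- simulate_counts(n_cells_per_group = 100, n_genes = 10000,
                         fold_change = 5, n_de = 1000, seed = 45)
  # deconvolution normalization: its pooled median factors resist the
  # composition shift that 10% strongly upregulated genes induce (a single
  # library-size factor would drag every null gene into significance)
  nm <- normalize_scran(sim$counts)
  scr <- de_screen(nm, sim$counts$condition, alpha = 0.05)
  expect_equal(formals(de_screen)$alpha, 0.05)
  precision <- mean(sim$truth$de_flags[scr$significant])
  expect_gte(precision, 0.8)
  expect_gt(scr$n_significant, 0)
})

test_that("the benchmark skips spike-in methods without spike-ins", {
  sim <- simulate_counts(n_cells_per_group = 10, n_genes = 300,
                         fold_change = 5, n_de = 60, seed = 3)
  cfg <- list(input = sim$counts,
              methods = c("simple", "samstrt", "scran", "grm"),
              clean = list(enabled = FALSE),
              n_repeats = 5, n_components = 10, seed = 2)
  report <- suppressWarnings(benchmark_run(cfg))
  expect_setequal(names(report$skipped), c("samstrt", "grm"))
  expect_setequal(unique(report$kappa$method), c("raw", "simple", "scran"))

  report2 <- suppressWarnings(benchmark_run(cfg))
  expect_identical(report$kappa, report2$kappa)  # seeded determinism

  g <- generics::glance(report)
  expect_true("raw" %in% g$method)
  expect_s3_class(generics::tidy(report), "tbl_df")
  expect_s3_class(ggplot2::autoplot(report), "ggplot")
})
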
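# Simple library-size scaling and spike-in depth normalization.

test_that("simple normalization matches its closed form", {
  cm <- count_matrix(matrix(c(1, 1, 2), 3, 1))
  nm <- normalize_simple(cm, scale_factor = 100)
  expect_equal(unname(nm$values[, 1]), log(c(26, 26, 51)),
               tolerance = 1e-12)
  expect_identical(nm$scale, "log")

  # zeros map to zero
  cm0 <- count_matrix(matrix(c(0, 4), 2, 1))
  expect_equal(normalize_simple(cm0)$values[1, 1], 0)

  # proportional columns normalize identically (depth invariance)
  cm2 <- count_matrix(matrix(c(3, 7, 9, 21), 2))
  nm2 <- normalize_simple(cm2)
  expect_equal(nm2$values[, 1], nm2$values[, 2], ignore_attr = TRUE)

  czero <- count_matrix(matrix(c(1, 0), 1), cell_ids = c("a", "dead"))
  expect_error(normalize_simple(czero), "dead")
})

test_that("within a cell, global-scaling outputs increase with raw counts", {
  base <- proportional_cm(n_cells = 25, n_genes = 40)
  counts <- rbind(base$counts, spike = round(colSums(base$counts) / 50))
  cm <- count_matrix(counts,
                     is_spikein = c(rep(FALSE, 40), TRUE))
  for (nm in list(normalize_simple(cm),
                  normalize_samstrt(cm, mode = "expected"),
                  normalize_scran(cm))) {
    ord <- order(cm$counts[, 3])
    expect_true(all(diff(nm$values[ord, 3]) >= 0))
  }
})

test_that("spike-in depth normalization uses the geometric-mean reference", {
  counts <- rbind(bio1 = c(10, 20, 30), spike = c(50, 50, 50))
  cm <- count_matrix(counts, is_spikein = c(FALSE, TRUE))
  nm <- normalize_samstrt(cm, mode = "expected")
  expect_equal(nm$values, cm$counts)   # equal spike totals: identity

  counts2 <- rbind(bio1 = c(8, 12), spike = c(100, 25))
  cm2 <- count_matrix(counts2, is_spikein = c(FALSE, TRUE))
  nm2 <- normalize_samstrt(cm2, mode = "expected")
  # geometric mean of spike totals is 50; cell 1 is 2x that, so halved
  expect_equal(unname(nm2$values[, 1]), c(4, 50))
  expect_equal(unname(nm2$values[, 2]), c(24, 50))

  no_spike <- count_matrix(matrix(1:4, 2))
  expect_error(normalize_samstrt(no_spike), "spike-in")
  dead <- count_matrix(rbind(c(5, 5), c(1, 0)),
                       is_spikein = c(FALSE, TRUE),
                       cell_ids = c("ok", "nospike"))
  expect_error(normalize_samstrt(dead), "nospike")
})

test_that("Poisson resampling is unbiased and seeded", {
  counts <- rbind(g1 = c(40, 9), g2 = c(7, 80), spike = c(30, 120))
  cm <- count_matrix(counts, is_spikein = c(FALSE, FALSE, TRUE))
  expected <- normalize_samstrt(cm, mode = "expected")$values
  res <- normalize_samstrt(cm, mode = "resample", n_resamples = 10000,
                           seed = 2)
  se <- sqrt(expected / 10000)
  expect_true(all(abs(res$values - expected) <= 3 * se + 1e-9))
  res2 <- normalize_samstrt(cm, mode = "resample", n_resamples = 10000,
                            seed = 2)
  expect_identical(res$values, res2$values)
})

test_that("stable-gene normalization degenerates to simple scaling at c = 0", {
  cm <- proportional_cm(n_cells = 12, n_genes = 50, seed = 3)
  out <- normalize_linnorm(cm, c = 0)
  lambda <- out$fit$lambda
  simple <- normalize_simple(cm, scale_factor = lambda)
  expect_equal(out$normalized$values, simple$values, tolerance = 1e-12)
  expect_equal(out$fit$a_updated, rep(1, 12))
  expect_equal(out$fit$b_updated, rep(0, 12))
})

test_that("normalization strength defaults to 0.5 and interpolates smoothly", {
  cm <- depth_effect_cm(n_genes = 40, n_cells = 12)
  fit <- normalize_linnorm(cm)$fit
  expect_equal(fit$c, 0.5)

  vals <- lapply(c(0, 0.25, 0.5, 0.75, 1),
                 function(cc) normalize_linnorm(cm, c = cc)$normalized$values)
  eps <- normalize_linnorm(cm, c = 0.5 + 1e-4)$normalized$values
  expect_lt(max(abs(eps - vals[[3]])), 1e-2)  # continuous in c
  step <- vapply(2:5, function(i) max(abs(vals[[i]] - vals[[i - 1]])), 1.0)
  expect_true(all(step < 2))  # no jumps along the path
  expect_error(normalize_linnorm(cm, c = 1.5), "\\[0, 1\\]")
})

test_that("identical cells get identical per-cell linear models", {
  col <- c(12, 40, 7, 90, 33, 21)
  m <- cbind(col, col, 2 * col)
  dimnames(m) <- NULL
  cm <- count_matrix(m)
  out <- normalize_linnorm(cm)
  expect_equal(out$fit$a[1], out$fit$a[2])
  expect_equal(out$fit$b[1], out$fit$b[2])
  expect_equal(out$normalized$values[, 1], out$normalized$values[, 2],
               ignore_attr = TRUE)
  # doubling a cell's counts leaves its relative scale, hence output,
  # unchanged
  expect_equal(out$normalized$values[, 1], out$normalized$values[, 3],
               ignore_attr = TRUE)
})

test_that("stable-gene selection fails loudly when nothing qualifies", {
  cm <- count_matrix(rbind(c(0, 5, 5), c(5, 0, 5), c(5, 5, 0)))
  expect_error(normalize_linnorm(cm), "stable")
})
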
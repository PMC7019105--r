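test_that("the model requires spike-ins and sane iteration settings", {
  cm <- count_matrix(matrix(rpois(40, 20), 4))
  expect_error(fit_basics(cm), "spike-in")
  expect_error(fit_basics(tiny_cm(), n_iter = 10, burn_in = 10), "burn_in")
})

test_that("chains are reproducible under a seed and phi sums to n", {
  dat <- basics_model_data(3, theta = 0.2, n_cells = 16, n_bio = 60,
                           n_spike = 8)
  f1 <- fit_basics(dat$cm, n_iter = 800, burn_in = 300, thin = 5, seed = 4)
  f2 <- fit_basics(dat$cm, n_iter = 800, burn_in = 300, thin = 5, seed = 4)
  expect_identical(f1$chains$theta, f2$chains$theta)
  expect_identical(f1$phi, f2$phi)
  expect_equal(rowSums(f1$chains$phi), rep(16, f1$diagnostics$n_kept))
  expect_true(all(f1$chains$theta > 0))
  expect_true(all(f1$chains$nu > 0))
})

test_that("vanishing technical noise drives theta's posterior toward zero", {
  dat <- basics_model_data(5, theta = 0, n_cells = 24, n_bio = 80,
                           n_spike = 8)
  f <- fit_basics(dat$cm, n_iter = 4000, burn_in = 2000, thin = 5, seed = 6)
  expect_lt(f$theta, 0.1)
})

test_that("spike-in parameters are insensitive to biological gene identity", {
  dat <- basics_model_data(9, theta = 0.3, n_cells = 20, n_bio = 100,
                           n_spike = 8)
  fit_ref <- function(cm, seed) {
    fit_basics(cm, n_iter = 3000, burn_in = 1500, thin = 5, seed = seed)
  }
  f_a <- fit_ref(dat$cm, 11)
  f_b <- fit_ref(dat$cm, 12)          # MCMC noise envelope
  env_nu <- max(abs(f_a$nu - f_b$nu)) + 1e-3
  env_theta <- abs(f_a$theta - f_b$theta) + 0.02

  perm <- withr::with_seed(2, sample(100))
  cm_perm <- subset_counts(dat$cm, genes = c(perm, 101:108))
  f_p <- fit_ref(cm_perm, 11)
  expect_lt(max(abs(f_p$nu - f_a$nu)), 3 * env_nu)
  expect_lt(abs(f_p$theta - f_a$theta), 3 * env_theta)
})

test_that("normalization removes cell-specific factors and shrinks CV", {
  dat <- basics_model_data(7, theta = 0.3, n_cells = 30, n_bio = 150,
                           n_spike = 8)
  f <- fit_basics(dat$cm, n_iter = 6000, burn_in = 3000, thin = 5, seed = 8)
  nm <- normalize_basics(f, dat$cm)
  expect_identical(nm$scale, "linear")
  expect_equal(nm$size_factors, f$phi * f$nu, ignore_attr = TRUE)

  bio <- !dat$cm$is_spikein
  cv2 <- function(m) {
    mu <- rowMeans(m)
    apply(m, 1, stats::var) / mu^2
  }
  raw_cv <- cv2(dat$cm$counts[bio, ])
  norm_cv <- cv2(nm$values[bio, ])
  expect_gte(mean(norm_cv < raw_cv), 0.8)

  # unit factors leave counts untouched; doubling phi halves a column
  f1 <- f
  f1$phi <- rep(1, 30); f1$nu <- rep(1, 30)
  expect_equal(normalize_basics(f1, dat$cm)$values, dat$cm$counts)
  f2 <- f1
  f2$phi[3] <- 2
  expect_equal(normalize_basics(f2, dat$cm)$values[bio, 3],
               dat$cm$counts[bio, 3] / 2, ignore_attr = TRUE)
})
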
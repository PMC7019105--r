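test_that("gamma regression interpolates a noiseless linear calibration", {
  x <- log(c(2, 5, 11, 25, 60, 140))
  fit <- fit_grm_cell(x, 1 + 2 * x, degrees = 1)
  expect_equal(fit$beta, c(1, 2), tolerance = 1e-6)
  expect_equal(fit$degree, 1)

  # with all candidate degrees available, ties in the zero-residual fit
  # resolve to the lowest degree
  fit_all <- fit_grm_cell(x, 1 + 2 * x, degrees = 1:4)
  expect_equal(fit_all$degree, 1)
  expect_equal(fit_all$beta, c(1, 2), tolerance = 1e-6)
})

test_that("all four candidate degrees are fitted with a full panel", {
  withr::with_seed(13, {
    x <- log(stats::rlnorm(92, 3, 1.2))
    mu <- 5 + 0.3 * x
    C <- stats::rgamma(92, shape = 50, rate = 50 / mu)
  })
  fit <- fit_grm_cell(x, C, degrees = 1:4)
  expect_setequal(names(fit$degree_scores), as.character(1:4))
})

test_that("coefficients recover within 3 SE in at least 90 of 100 runs", {
  hits <- 0
  for (rep_i in 1:100) {
    withr::with_seed(1000 + rep_i, {
      x <- stats::runif(92, 0.5, 6)
      mu <- 2 + 0.5 * x
      C <- stats::rgamma(92, shape = 50, rate = 50 / mu)
    })
    fit <- fit_grm_cell(x, C, degrees = 1)
    se <- sqrt(pmax(diag(fit$vcov), 0))
    if (all(is.finite(se)) &&
        all(abs(fit$beta - c(2, 0.5)) <= 3 * se)) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("spike-ins below the parameter count are rejected", {
  expect_error(fit_grm_cell(c(1, 2), c(1, 2), degrees = 1:4),
               "usable spike-ins")
})

test_that("per-cell normalization is local and interpolates spike-ins", {
  fx <- grm_linear_fixture()
  nm <- normalize_grm(fx$cm, fx$ref)
  # noiseless linear calibration: a biological gene whose FPKM matches a
  # spike-in gets that spike-in's known log concentration
  fpkm <- compute_fpkm(fx$cm)
  expect_equal(unname(nm$values[, 1]),
               unname(fx$b0 + fx$b1 * log(fpkm[!fx$cm$is_spikein, 1])),
               tolerance = 1e-6)
  # columns are proportional counts, so FPKM and outputs agree across cells
  expect_equal(nm$values[, 1], nm$values[, 2], ignore_attr = TRUE,
               tolerance = 1e-6)

  # locality: perturbing cell 2's counts leaves cell 1's output untouched
  cm2 <- fx$cm
  cm2$counts[1, 2] <- cm2$counts[1, 2] + 57
  cm2 <- validate_count_matrix(cm2)
  nm2 <- normalize_grm(cm2, fx$ref)
  expect_identical(nm$values[, 1], nm2$values[, 1])

  # positive-slope degree-1 fit implies monotonicity in FPKM within a cell
  ord <- order(fpkm[!fx$cm$is_spikein, 1])
  expect_true(all(diff(nm$values[ord, 1]) > 0))
})

test_that("zero counts normalize to zero and are flagged", {
  fx <- grm_linear_fixture()
  cm <- fx$cm
  cm$counts[2, 1] <- 0
  cm <- validate_count_matrix(cm)
  nm <- normalize_grm(cm, fx$ref)
  expect_equal(nm$values[2, 1], 0)
  expect_true(attr(nm, "zero_flag")[2, 1])
})

test_that("cells without detected spike-ins abort with the cell named", {
  fx <- grm_linear_fixture()
  cm <- fx$cm
  cm$counts[cm$is_spikein, 2] <- 0
  cm <- validate_count_matrix(cm)
  expect_error(normalize_grm(cm, fx$ref), "c2")
})
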
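test_that("univariate KDE matches hand-computed values", {
  expect_equal(kde_univariate(0, 1, 0), 1 / sqrt(2 * pi))
  expect_lt(kde_univariate(0, 1, 1e6), 1e-300)
  expect_equal(kde_univariate(c(-1, 1), 1, 0), exp(-0.5) / sqrt(2 * pi))
  # bandwidth scaling and averaging over kernels
  expect_equal(kde_univariate(0, 2, 0), 1 / (2 * sqrt(2 * pi)))
})

test_that("bivariate KDE matches hand-computed values", {
  expect_equal(kde_bivariate(0, 0, 1, 0, 0), 1 / (2 * pi))
  expect_equal(kde_bivariate(0, 0, 2, 0, 0), 1 / (8 * pi))
})

test_that("KDE rejects invalid bandwidths and empty samples", {
  expect_error(kde_univariate(c(1, 2), 0, 0), "positive")
  expect_error(kde_univariate(c(1, 2), -1, 0), "positive")
  expect_error(kde_univariate(numeric(), 1, 0), "empty")
  expect_error(kde_bivariate(numeric(), numeric(), 1, 0, 0), "empty")
  expect_error(kde_bivariate(1:3, 1:2, 1, 0, 0), "equal length")
  expect_error(ucv_objective_1d(1, 1), "at least 2")
  expect_error(ucv_objective_2d(1, 1, 1), "at least 2")
})

test_that("KDE densities are non-negative and integrate to one", {
  set.seed(42)
  for (k in 1:5) {
    x <- rnorm(30, sd = runif(1, 0.5, 2))
    h <- runif(1, 0.1, 1)
    q <- seq(min(x) - 6 * h, max(x) + 6 * h, length.out = 2000)
    f <- kde_univariate(x, h, q)
    expect_true(all(f >= 0))
    expect_equal(sum(f) * diff(q[1:2]), 1, tolerance = 1e-3)
  }
  # bivariate: grid quadrature over a +/- 6h padded square
  x <- rnorm(20); y <- rnorm(20); h <- 0.5
  gx <- seq(min(x) - 6 * h, max(x) + 6 * h, length.out = 200)
  gy <- seq(min(y) - 6 * h, max(y) + 6 * h, length.out = 200)
  gr <- expand.grid(gx = gx, gy = gy)
  f <- kde_bivariate(x, y, h, gr$gx, gr$gy)
  expect_true(all(f >= 0))
  expect_equal(sum(f) * diff(gx[1:2]) * diff(gy[1:2]), 1, tolerance = 1e-3)
})

test_that("UCV objectives match hand evaluations including degenerate ties", {
  expect_equal(ucv_objective_1d(c(-1, 1), 1),
               (1 + exp(-1)) / (4 * sqrt(pi)) - exp(-2) * sqrt(2 / pi),
               tolerance = 1e-10)
  expect_equal(ucv_objective_1d(c(-1, 1), 1), 0.08495, tolerance = 1e-4)
  expect_equal(ucv_objective_1d(c(0, 0), 1),
               1 / (2 * sqrt(pi)) - 2 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(ucv_objective_2d(c(0, 0), c(0, 0), 1),
               1 / (4 * pi) - 1 / pi, tolerance = 1e-12)
})

test_that("UCV objectives agree with quadrature plus leave-one-out oracles", {
  set.seed(7)
  for (k in 1:5) {
    x <- rnorm(15); h <- runif(1, 0.2, 0.8)
    expect_lt(rel_err(ucv_objective_1d(x, h), ucv1_naive(x, h)), 1e-6)
  }
  x <- rnorm(12); y <- rnorm(12)
  expect_lt(rel_err(ucv_objective_2d(x, y, 0.5), ucv2_naive(x, y, 0.5)), 1e-5)
})

test_that("UCV objective is finite and smooth in h with an interior minimum", {
  set.seed(11)
  x <- rnorm(200); y <- rnorm(200)
  hs <- exp(seq(log(0.05), log(2), length.out = 30))
  obj <- vapply(hs, function(h) ucv_objective_2d(x, y, h), numeric(1))
  expect_true(all(is.finite(obj)))
  i <- which.min(obj)
  expect_gt(i, 1)
  expect_lt(i, length(hs))
  # also finite over an extreme range
  expect_true(is.finite(ucv_objective_1d(x, 1e-3)))
  expect_true(is.finite(ucv_objective_1d(x, 10)))
})

test_that("bandwidth selection is deterministic and sane for Gaussian data", {
  set.seed(3)
  v <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(NULL, c(paste0("i", 1:4), "o1", "o2")))
  sm <- sample_matrix(v, c(rep("input", 4), rep("output", 2)))
  bw1 <- select_bandwidth(sm, n_pairs = 5, seed = 9)
  bw2 <- select_bandwidth(sm, n_pairs = 5, seed = 9)
  expect_identical(bw1$h, bw2$h)
  expect_equal(bw1$h, mean(bw1$per_pair_h))
  # standard-Gaussian pairs at n = 200: optimum brackets the Silverman
  # reference 1.06 * n^(-1/5) ~ 0.37
  expect_gt(bw1$h, 0.15)
  expect_lt(bw1$h, 0.70)
})

test_that("n_pairs = 1 returns that pair's own UCV optimum and clamping warns", {
  set.seed(5)
  v <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "y")))
  sm <- sample_matrix(v, c("input", "input", "output"))
  bw <- select_bandwidth(sm, n_pairs = 1, seed = 2)
  expect_length(bw$per_pair_h, 1)
  expect_identical(bw$h, unname(bw$per_pair_h[1]))
  expect_warning(select_bandwidth(sm, n_pairs = 50, seed = 2), "exceeds")
})

test_that("bandwidth selection over all pairs is invariant to column order", {
  set.seed(8)
  v <- matrix(rnorm(80 * 4), 80, 4,
              dimnames = list(NULL, c("a", "b", "y1", "y2")))
  sm1 <- sample_matrix(v, c("input", "input", "output", "output"))
  v2 <- v[, c(2, 1, 4, 3)]
  sm2 <- sample_matrix(v2, c("input", "input", "output", "output"))
  b1 <- select_bandwidth(sm1, seed = 1)
  b2 <- select_bandwidth(sm2, seed = 1)
  expect_equal(b1$h, b2$h, tolerance = 1e-12)
})
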
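test_that("k-NN entropy matches closed forms for uniform and Gaussian", {
  set.seed(31)
  expect_lt(abs(knn_entropy(runif(1e4), 3)), 0.03)          # ln(1) = 0
  expect_equal(knn_entropy(rnorm(1e4), 3), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.03)
})

test_that("duplicate points error out unless jitter is enabled", {
  x <- c(1, 1, 2, 3, 4, 5)
  expect_error(knn_entropy(x, 1), "duplicate")
  expect_true(is.finite(knn_entropy(x, 1, jitter_scale = 1)))
  expect_error(knn_entropy(rnorm(10), 10), "k must satisfy")
})

test_that("k-NN MI is calibrated on Gaussians and exactly symmetric", {
  set.seed(32)
  n <- 4000
  z <- rnorm(n)
  y <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
  expect_equal(knn_mi(z, y, 3), -0.5 * log(1 - 0.81), tolerance = 0.05)

  # independence: near zero at small k; the variance-oriented k = n/2
  # setting carries a known downward offset that stays bounded
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(knn_mi(a, b, 3)), 0.05)
  expect_lt(abs(knn_mi(a, b, 500)), 0.25)

  # 3H formula is symmetric in its arguments
  expect_identical(knn_mi(z[1:500], y[1:500], 5),
                   knn_mi(y[1:500], z[1:500], 5))

  # clipping floors negative estimates at zero
  expect_gte(knn_mi(a, b, 500, clip_negative = TRUE), 0)
})

test_that("k-NN MI is invariant to axis-wise affine rescaling", {
  set.seed(33)
  n <- 1000
  z <- rnorm(n)
  y <- 0.7 * z + sqrt(1 - 0.49) * rnorm(n)
  m1 <- knn_mi(z, y, 3)
  m2 <- knn_mi(3 * z - 3, 0.5 * y + 11, 3)
  expect_lt(abs(m1 - m2), 0.05)
})

test_that("fixed-bin histogram MI handles dependence, independence, sign", {
  set.seed(34)
  # two well-separated equal clusters with x = y: the induced 2x2 table is
  # diagonal with mass 1/2 + 1/2, so plug-in MI = ln 2
  x <- c(rnorm(500, 0, 0.01), rnorm(500, 10, 0.01))
  expect_equal(histogram_mi_fixed(x, x, 2), log(2), tolerance = 1e-12)

  u <- runif(1e4); v <- runif(1e4)
  expect_lt(histogram_mi_fixed(u, v, 2), 0.01)

  # plug-in MI is non-negative for arbitrary inputs
  for (i in 1:20) {
    a <- rnorm(60); b <- rnorm(60)
    expect_gte(histogram_mi_fixed(a, b, 2), 0)
    expect_gte(histogram_mi_adaptive(a, b, 3), 0)
  }

  expect_warning(histogram_mi_fixed(rep(1, 50), rnorm(50)), "constant axis")
})

test_that("adaptive bins are equal-occupancy and rank invariant", {
  set.seed(35)
  x <- rnorm(101); y <- rnorm(101)
  m1 <- histogram_mi_adaptive(x, y, 3)
  # strictly monotone transforms preserve ranks, hence the estimate
  m2 <- histogram_mi_adaptive(exp(x), atan(y), 3)
  expect_identical(m1, m2)

  b <- mift:::.bin_adaptive(x, 3)
  expect_lte(diff(range(table(b))), 1)

  u <- runif(5000); v <- runif(5000)
  expect_lt(histogram_mi_adaptive(u, v, 3), 0.01)
})

test_that("sample kurtosis matches known distributions and is scale free", {
  set.seed(36)
  expect_equal(sample_kurtosis(rnorm(1e5)), 3, tolerance = 0.05)
  # Uniform(-0.5, 0.5) itself has kurtosis 9/5
  u <- runif(1e5, -0.5, 0.5)
  expect_equal(sample_kurtosis(u), 1.8, tolerance = 0.02)
  expect_equal(sample_kurtosis(u), sample_kurtosis(250 * u),
               tolerance = 1e-12)
  expect_error(sample_kurtosis(rep(2, 10)), "zero variance")
  expect_error(sample_kurtosis(1:3), "at least 4")
})
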
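test_that("window z-scoring matches the closed form and is affine-invariant", {
  nz <- normalize_series(c(0, 1, 2, 3, 4))
  expect_equal(nz$values,
               c(-sqrt(2), -sqrt(2) / 2, 0, sqrt(2) / 2, sqrt(2)))
  expect_equal(mean(nz$values), 0)
  expect_equal(sqrt(mean(nz$values^2)), 1)

  set.seed(2)
  x <- rnorm(30)
  a <- normalize_series(x)
  b <- normalize_series(3.7 * x + 11)
  expect_equal(a$values, b$values, tolerance = 1e-12)

  expect_error(normalize_series(rep(2, 10)), "zero variance")
  expect_error(normalize_series(c(1, 2), times = c(0, 1)), "3 samples")
  # window restriction
  w <- normalize_series(x, times = seq(0, 29), window = c(5, 14))
  expect_identical(w$indices, 6:15)
})

test_that("an impulse reproduces the wavelet shape, peaking at its index", {
  n <- 64
  x <- numeric(n)
  k <- 30
  x[k] <- 1
  scales <- c(2, 5, 11)
  sc <- ricker_cwt(x, scales = scales)
  idx <- seq_len(n)
  for (si in seq_along(scales)) {
    oracle <- ricker_wavelet(k - idx, scales[si])  # direct convolution
    expect_equal(sc$C[si, ], oracle, tolerance = 1e-12)
    expect_identical(which.max(sc$C[si, ]), as.integer(k))
  }
  expect_equal(max(abs(ricker_cwt(numeric(n), scales = scales)$C)), 0)
})

test_that("an embedded Ricker pulse is localized in time and scale", {
  n <- 120
  scales <- default_scales(n)
  s0 <- scales[17]
  t0 <- 60
  x <- ricker_wavelet(seq_len(n) - t0, s0)
  sc <- ricker_cwt(x, scales = scales)
  ev <- find_events(sc, min_separation = 5)
  expect_identical(ev$time_index[1], as.integer(t0))
  # scale recovered within one grid step (grid-search oracle)
  si <- which(abs(scales - ev$scale[1]) < 1e-12)
  expect_lte(abs(si - 17), 1)
})

test_that("the transform is linear and shift-covariant", {
  n <- 80
  set.seed(7)
  x <- rnorm(n)
  y <- rnorm(n)
  scales <- default_scales(n, 12)
  cx <- ricker_cwt(x, scales = scales)$C
  cy <- ricker_cwt(y, scales = scales)$C
  cxy <- ricker_cwt(2 * x - 3 * y, scales = scales)$C
  expect_equal(cxy, 2 * cx - 3 * cy, tolerance = 1e-12)

  k <- 9
  sc_cov <- c(1, 1.5, 3)
  margin <- ceiling(8 * max(sc_cov)) + k  # Gaussian tails < 1e-14
  xs <- c(numeric(k), x[seq_len(n - k)])
  cs <- ricker_cwt(xs, scales = sc_cov)$C
  cx2 <- ricker_cwt(x, scales = sc_cov)$C
  interior <- (margin + 1):(n - margin)
  expect_equal(cs[, interior], cx2[, interior - k], tolerance = 1e-10)
})

test_that("non-uniform sampling is rejected", {
  expect_error(ricker_cwt(rnorm(10), times = c(1:9, 11)), "non-uniform")
})

test_that("event extraction suppresses near-duplicates and orders by strength", {
  n <- 150
  scales <- default_scales(n)
  s0 <- scales[14]
  x <- ricker_wavelet(seq_len(n) - 40, s0) +
    0.6 * ricker_wavelet(seq_len(n) - 100, s0)
  sc <- ricker_cwt(x, scales = scales)
  ev <- find_events(sc, min_separation = 20)
  expect_gte(nrow(ev), 2)
  expect_identical(ev$time_index[1:2], c(40L, 100L))
  expect_true(abs(ev$coefficient[1]) >= abs(ev$coefficient[2]))
  # an empty scalogram yields an empty event list
  sc0 <- ricker_cwt(numeric(20), scales = c(2, 4))
  expect_identical(nrow(find_events(sc0)), 0L)
})
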
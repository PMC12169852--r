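sym_coeffs <- function(lmax, seed = 42) {
  set.seed(seed)
  n <- (lmax + 1)^2
  ct <- complex(real = rnorm(n), imaginary = rnorm(n))
  for (l in 0:lmax) {
    ct[sh_index(l, 0)] <- Re(ct[sh_index(l, 0)])
    for (m in seq_len(l))
      ct[sh_index(l, -m)] <- (-1)^m * Conj(ct[sh_index(l, m)])
  }
  ct
}

test_that("constant field projects onto Y00 only", {
  m <- ico(4)
  Y <- sh_basis(m$theta, m$phi, 4)
  w <- vertex_area_weights(m)
  co <- sh_forward(rep(1, nrow(m$vertices)), Y, w)
  expect_equal(Re(co[1]), sqrt(4 * pi), tolerance = 0.005)
  expect_lt(max(Mod(co[-1])), 1e-2)
})

test_that("sampled Y10 is recovered with unit coefficient", {
  m <- ico(4)
  Y <- sh_basis(m$theta, m$phi, 4)
  w <- vertex_area_weights(m)
  f <- sqrt(3 / (4 * pi)) * cos(m$theta)  # Y10
  co <- sh_forward(f, Y, w)
  expect_equal(Re(co[sh_index(1, 0)]), 1, tolerance = 0.01)
  expect_lt(max(Mod(co[-sh_index(1, 0)])), 1e-2)
})

test_that("basis is discretely orthonormal and conjugate-symmetric", {
  m <- ico(4)
  Y <- sh_basis(m$theta, m$phi, 8)
  w <- vertex_area_weights(m)
  G <- t(Conj(Y)) %*% (Y * w)
  expect_lt(max(Mod(G - diag(ncol(Y)))), 1e-2)
  for (l in 1:3)
    for (mm in 1:l)
      expect_lt(max(Mod(Y[, sh_index(l, -mm)] -
                        (-1)^mm * Conj(Y[, sh_index(l, mm)]))), 1e-12)
})

test_that("band-limited fields round-trip through the transform", {
  m <- ico(4)
  Y <- sh_basis(m$theta, m$phi, 8)
  w <- vertex_area_weights(m)
  ct <- sym_coeffs(8)
  f <- sh_reconstruct(ct, Y)
  expect_true(is.numeric(f))  # conjugate-symmetric input -> real field
  cr <- sh_forward(f, Y, w)
  expect_lt(sqrt(sum(Mod(cr - ct)^2) / sum(Mod(ct)^2)), 0.01)
  # Parseval at band limit: coefficient energy matches field energy
  expect_equal(sum(Mod(ct)^2), sum(f^2 * w), tolerance = 0.02)
})

test_that("reconstruction handles trivial coefficient vectors", {
  m <- ico(2)
  Y <- sh_basis(m$theta, m$phi, 3)
  expect_equal(sh_reconstruct(rep(0 + 0i, 16), Y),
               rep(0, nrow(m$vertices)))
  c00 <- c(sqrt(4 * pi) + 0i, rep(0 + 0i, 15))
  expect_equal(sh_reconstruct(c00, Y), rep(1, nrow(m$vertices)),
               tolerance = 1e-12)
  expect_error(sh_reconstruct(rep(0 + 0i, 9), Y), "missing")
})

test_that("forward transform is linear and guards against aliasing", {
  m <- ico(2)
  Y <- sh_basis(m$theta, m$phi, 3)
  w <- vertex_area_weights(m)
  set.seed(5)
  f1 <- rnorm(nrow(m$vertices))
  f2 <- rnorm(nrow(m$vertices))
  expect_equal(sh_forward(2 * f1 - 5 * f2, Y, w),
               2 * sh_forward(f1, Y, w) - 5 * sh_forward(f2, Y, w),
               tolerance = 1e-12)
  Ybig <- sh_basis(m$theta, m$phi, 11)  # 144 coeffs from 162 vertices
  expect_warning(sh_forward(f1, Ybig, w), "aliasing")
})

test_that("variance ratios are magnitude shares summing to one", {
  hs <- structure(list(times = 1:2, lmax = 2L,
                       coeffs = matrix(0 + 0i, 9, 2),
                       degrees = sh_degrees(2),
                       basis = "complex_orthonormal"),
                  class = "harmonic_series")
  hs$coeffs[sh_index(1, 0), 1] <- 3
  hs$coeffs[sh_index(0, 0), 2] <- 2i
  hs$coeffs[sh_index(2, 1), 2] <- 2
  vr <- variance_ratios(hs)
  expect_equal(vr$per_frame[sh_index(1, 0), 1], 1)
  expect_equal(sum(vr$per_frame[, 1]), 1)
  expect_equal(vr$per_frame[sh_index(0, 0), 2], 0.5)
  expect_equal(vr$per_frame[sh_index(2, 1), 2], 0.5)
  # all-zero frame -> NA with a message
  hs$coeffs[, 1] <- 0
  expect_message(vr0 <- variance_ratios(hs), "all-zero")
  expect_true(all(is.na(vr0$per_frame[, 1])))
  expect_equal(sum(vr0$per_frame[, 2]), 1)
})

test_that("real basis is orthonormal and drives real radii", {
  m <- ico(3)
  Yr <- sh_real_basis(m$theta, m$phi, 4)
  expect_true(is.numeric(Yr))
  w <- vertex_area_weights(m)
  G <- t(Yr) %*% (Yr * w)
  expect_lt(max(abs(G - diag(ncol(Yr)))), 1e-2)
})
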
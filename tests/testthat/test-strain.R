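test_that("velocity field matches analytic derivatives of a pulsation", {
  base <- ico(2)
  eps <- 0.05
  script <- deformation_script(
    n_frames = 40, dt = 1 / 30, R0 = 60, seed = 3,
    global_amplitude = function(t) eps * sin(2 * pi * t))
  sim <- make_deforming_sphere(script, base)
  vel <- velocity_field(sim$surface)
  # interior frames: central difference error is O(dt^2)
  k <- 10
  analytic <- sim$truth$velocities[k, , ]
  expect_lt(max(abs(vel[k, , ] - analytic)),
            60 * eps * (2 * pi)^3 * (1 / 30)^2)
  # static surface and uniform translation
  st <- evolving_surface(c(0, 1, 2),
                         array(rep(base$vertices, each = 3), c(3, nrow(base$vertices), 3)),
                         base$faces)
  expect_equal(max(abs(velocity_field(st))), 0)
  tr <- st
  for (k in 1:3) tr$positions[k, , 1] <- tr$positions[k, , 1] + (k - 1) * 2
  vtr <- velocity_field(tr)
  expect_equal(range(vtr[, , 1]), c(2, 2))
  expect_equal(max(abs(vtr[, , 2:3])), 0)
})

test_that("velocity field rejects duplicate timestamps", {
  base <- ico(1)
  es <- evolving_surface(c(0, 1), array(rep(base$vertices, each = 2),
                                        c(2, nrow(base$vertices), 3)),
                         base$faces)
  es$times <- c(1, 1)
  expect_error(velocity_field(es), "duplicate")
})

test_that("strain tensor reproduces the tangential expansion oracle", {
  m <- ico(4)
  c0 <- 0.7
  D <- strain_rate_tensor(m$vertices, m$faces, c0 * m$vertices)
  f <- scalar_strain_rate(D)
  expect_lt(max(abs(f - c0 * sqrt(2))) / (c0 * sqrt(2)), 0.05)
  ev <- strain_eigen(D[1:20, , ])
  expect_equal(ev$values[, 1], rep(c0, 20), tolerance = 0.01)
  expect_equal(ev$values[, 2], rep(c0, 20), tolerance = 0.01)
  expect_equal(ev$values[, 3], rep(0, 20), tolerance = 0.01 * c0)
})

test_that("rigid motions produce negligible strain", {
  m <- ico(4)
  c0 <- 0.7
  ref <- c0 * sqrt(2)
  # translation: exactly zero gradient
  Dt <- strain_rate_tensor(m$vertices, m$faces,
                           matrix(rep(c(1, 2, 3), each = nrow(m$vertices)),
                                  ncol = 3))
  expect_lt(max(abs(Dt)), 1e-12)
  # rotation at matched velocity magnitude: scalar at least 100x below the
  # expansion reference, and small relative to the raw gradient
  vel <- rotation_velocity(m$vertices, c(c0, 0, 0))
  Dr <- strain_rate_tensor(m$vertices, m$faces, vel)
  fr <- scalar_strain_rate(Dr)
  expect_lt(max(fr), ref / 100)
  G <- attr(Dr, "G")
  expect_lt(mean(fr), 0.01 * mean(scalar_strain_rate(G)))
})

test_that("strain is translation-invariant and scales with velocity", {
  m <- ico(2)
  set.seed(11)
  vel <- matrix(rnorm(nrow(m$vertices) * 3), ncol = 3)
  D <- strain_rate_tensor(m$vertices, m$faces, vel)
  Dshift <- strain_rate_tensor(m$vertices, m$faces,
                               sweep(vel, 2, c(5, -2, 7), "+"))
  expect_lt(max(abs(D - Dshift)), 1e-10 * max(abs(D)))
  D3 <- strain_rate_tensor(m$vertices, m$faces, 3 * vel)
  expect_equal(D3, 3 * D, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(scalar_strain_rate(D3), 3 * scalar_strain_rate(D),
               tolerance = 1e-12)
})

test_that("scalar strain rate equals the Frobenius norm", {
  expect_equal(scalar_strain_rate(array(diag(c(3, 4, 0)), c(1, 3, 3))), 5)
  set.seed(4)
  D <- array(0, c(10, 3, 3))
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3)
    D[i, , ] <- (A + t(A)) / 2
  }
  frob <- vapply(1:10, function(i) sqrt(sum(D[i, , ]^2)), numeric(1))
  expect_equal(scalar_strain_rate(D), frob, tolerance = 1e-10)
  ev <- strain_eigen(D)
  expect_equal(sqrt(rowSums(ev$values^2)), frob, tolerance = 1e-10)
})

test_that("expansion-oracle error shrinks with refinement", {
  c0 <- 0.5
  dev <- vapply(c(3, 5), function(lvl) {
    m <- ico(lvl)
    f <- scalar_strain_rate(strain_rate_tensor(m$vertices, m$faces,
                                               c0 * m$vertices))
    max(abs(f - c0 * sqrt(2)))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
})

test_that("ring Gaussian smoothing normalizes, conserves and contracts", {
  m <- ico(3)
  nv <- nrow(m$vertices)
  # constant field unchanged
  expect_equal(smooth_field(rep(2.5, nv), m$faces, 1, NULL), rep(2.5, nv))
  # delta at a regular vertex whose 2-ring is regular: mass conserved
  valence <- tabulate(as.integer(m$edges), nv)
  rings <- ring_neighbors(m$faces, nv)
  reg <- which(vapply(seq_len(nv), function(v)
    valence[v] == 6L &&
      all(valence[c(rings$ring1[[v]], rings$ring2[[v]])] == 6L),
    logical(1)))[1]
  delta <- numeric(nv)
  delta[reg] <- 1
  out <- smooth_field(delta, m$faces, 1, NULL)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_equal(sum(out[c(reg, rings$ring1[[reg]], rings$ring2[[reg]])]), 1,
               tolerance = 1e-12)
  # white noise: variance strictly reduced, across 100 seeded draws
  reduced <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(nv)
    var(smooth_field(x, m$faces, 1, NULL)) < var(x)
  }, logical(1))
  expect_true(all(reduced))
})

test_that("smoothing is linear and preserves tensor symmetry", {
  m <- ico(2)
  nv <- nrow(m$vertices)
  set.seed(8)
  A <- array(rnorm(3 * nv * 9), c(3, nv, 3, 3))
  A <- (A + aperm(A, c(1, 2, 4, 3))) / 2
  B <- array(rnorm(3 * nv * 9), c(3, nv, 3, 3))
  sAB <- smooth_field(2 * A + 3 * B, m$faces)
  expect_equal(sAB, 2 * smooth_field(A, m$faces) +
                 3 * smooth_field(B, m$faces), tolerance = 1e-12)
  sA <- smooth_field(A, m$faces)
  expect_lt(max(abs(sA - aperm(sA, c(1, 2, 4, 3)))), 1e-14)
  expect_error(smooth_field(A, m$faces, spatial_sigma = 0), "sigma")
  expect_error(smooth_field(A, m$faces, temporal_sigma = -1), "sigma")
})

test_that("strain_field smooths before deriving the scalar", {
  base <- ico(2)
  sim <- make_deforming_sphere(default_pulsation_script(n_frames = 8),
                               base)
  sf <- strain_field(sim$surface)
  expect_equal(sf$scalar, scalar_strain_rate(sf$D), tolerance = 1e-12)
  expect_lt(max(abs(sf$D - aperm(sf$D, c(1, 2, 4, 3)))), 1e-10)
  expect_true(all(sf$scalar >= 0))
})
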
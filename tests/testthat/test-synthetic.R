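test_that("the generator is deterministic given script and seed", {
  base <- ico(2)
  script <- deformation_script(n_frames = 6, noise_sigma = 0.3, seed = 17,
                               global_amplitude = function(t) 0.04 * sin(t))
  a <- make_deforming_sphere(script, base)
  b <- make_deforming_sphere(script, base)
  expect_identical(a$surface$positions, b$surface$positions)
  expect_identical(a$truth$velocities, b$truth$velocities)
})

test_that("an empty script yields a static sphere with zero velocity", {
  base <- ico(2)
  sim <- make_deforming_sphere(deformation_script(n_frames = 4, R0 = 10),
                               base)
  for (k in 2:4)
    expect_equal(frame_positions(sim$surface, k),
                 frame_positions(sim$surface, 1))
  expect_equal(max(abs(sim$truth$velocities)), 0, tolerance = 1e-6)
})

test_that("pulse schedules define the ground-truth event times", {
  base <- ico(1)
  ps <- data.frame(t_center = c(0.4, 1.2), width = c(0.05, 0.05),
                   amplitude = c(0.03, 0.05))
  sim <- make_deforming_sphere(
    deformation_script(n_frames = 10, pulse_schedule = ps), base)
  expect_equal(sim$truth$event_times, c(0.4, 1.2))
})

test_that("overdriven scripts error instead of inverting the surface", {
  base <- ico(1)
  bad <- deformation_script(n_frames = 3,
                            global_amplitude = function(t) -1 - t)
  expect_error(make_deforming_sphere(bad, base), "script error")
  expect_error(make_invagination_embryo(function(t) 100, n_frames = 3,
                                        R0 = 60, base = base),
               "script error")
})

test_that("analytic velocities match finite differences at O(dt^2)", {
  base <- ico(2)
  for (dt in c(1 / 15, 1 / 30)) {
    sim <- make_deforming_sphere(deformation_script(
      n_frames = 20, dt = dt, R0 = 60,
      global_amplitude = function(t) 0.05 * sin(2 * pi * t)), base)
    vel <- velocity_field(sim$surface)
    interior <- 2:19
    err <- max(abs(vel[interior, , ] - sim$truth$velocities[interior, , ]))
    # central difference error bound: |v'''| h^2 / 6
    bound <- 60 * 0.05 * (2 * pi)^3 * dt^2 / 6 * 1.1
    expect_lt(err, bound)
  }
})

test_that("generated surfaces stay embedded", {
  base <- ico(2)
  sim <- make_deforming_sphere(default_pulsation_script(n_frames = 5),
                               base)
  for (k in 1:5)
    expect_identical(nrow(self_intersections(
      frame_positions(sim$surface, k), sim$surface$faces)), 0L)
  inv <- make_invagination_embryo(two_phase_depth(20, 0.4, 0.1, 20, 1.2, 0.1),
                                  n_frames = 5, dt = 0.4, R0 = 60,
                                  base = base)
  for (k in 1:5)
    expect_identical(nrow(self_intersections(
      frame_positions(inv$surface, k), inv$surface$faces)), 0L)
})

test_that("invagination localizes strain inside the cap", {
  base <- ico(3)
  dep <- two_phase_depth(10, 0.5, 0.1, 10, 1.5, 0.1)
  sim <- make_invagination_embryo(dep, cap_angle = pi / 4, n_frames = 30,
                                  dt = 1 / 15, R0 = 60, base = base)
  expect_equal(sim$truth$event_times, c(0.5, 1.5))
  sf <- strain_field(sim$surface)
  k <- which.min(abs(sim$surface$times - 0.5))  # first ramp midpoint
  cap <- sim$truth$cap_vertices
  expect_gt(mean(sf$scalar[k, cap]), 3 * mean(sf$scalar[k, -cap]))
})

test_that("a 3-cell tessellation has two antipodal triple points", {
  m <- ico(3)
  tess <- make_cell_tessellation(60 * m$vertices, m$faces, 3, seed = 2)
  expect_identical(nrow(tess$junctions), 2L)
  p1 <- as.numeric(tess$junctions[1, c("x", "y", "z")])
  p2 <- as.numeric(tess$junctions[2, c("x", "y", "z")])
  # antipodal within the patch resolution
  expect_lt(sum(p1 * p2) / (sqrt(sum(p1^2)) * sqrt(sum(p2^2))), -0.8)

  # brute-force oracle: spherical Voronoi vertices of the 3 seeds are the
  # two unit cross-product directions of the seed-difference vectors
  s <- tess$seeds
  n <- c(pracma::cross(s[2, ] - s[1, ], s[3, ] - s[1, ]))
  n <- n / sqrt(sum(n^2))
  cosang <- abs(sum(p1 / sqrt(sum(p1^2)) * n))
  expect_gt(cosang, 0.95)
})

test_that("tessellation cells are closed and junction members >= 3", {
  m <- ico(3)
  tess <- make_cell_tessellation(60 * m$vertices, m$faces, 8, seed = 4)
  for (cl in tess$cells) {
    expect_true(is_closed_mesh(cl$faces)$closed)
    expect_true(all(cl$apical <= nrow(cl$faces)))
  }
  expect_true(all(tess$junctions$n_members >= 3))
  expect_true(all(lengths(attr(tess$junctions, "members")) >= 3))
  expect_error(make_cell_tessellation(60 * m$vertices, m$faces, 2),
               ">= 3")
  expect_error(make_cell_tessellation(60 * m$vertices, m$faces, 200),
               "under-resolved")
})
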
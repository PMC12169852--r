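test_that("enclosing sphere shrinks onto spherical and ellipsoidal targets", {
  base <- ico(3)
  tgt <- ico(4)
  fit <- fit_surface(list(vertices = tgt$vertices, faces = tgt$faces),
                     2 * base$vertices, base$faces,
                     warn_not_enclosing = FALSE)
  expect_true(fit$converged)
  expect_lt(fit$residuals$max, fit$tol)
  r <- sqrt(rowSums(fit$vertices^2))
  expect_true(all(abs(r - 1) < fit$tol))

  # ellipsoid (2, 1, 1): residual also measured against the analytic
  # implicit surface g = (x/2)^2 + y^2 + z^2 - 1 via |g| / |grad g|
  ell <- list(vertices = tgt$vertices %*% diag(c(2, 1, 1)),
              faces = tgt$faces)
  fe <- fit_surface(ell, 3 * base$vertices, base$faces,
                    warn_not_enclosing = FALSE)
  expect_true(fe$converged)
  expect_lt(fe$residuals$mean, fe$tol)
  v <- fe$vertices
  g <- (v[, 1] / 2)^2 + v[, 2]^2 + v[, 3]^2 - 1
  gr <- sqrt((v[, 1] / 2)^2 + 4 * v[, 2]^2 + 4 * v[, 3]^2)
  expect_lt(mean(abs(g) / gr), fe$tol)
  # topology preserved, no flipped faces
  expect_identical(dim(fe$vertices), dim(base$vertices))
  fa <- face_normals_areas(fe$vertices, base$faces)
  expect_true(all(rowSums(fa$normals * fa$centroids) > 0))
})

test_that("fit residuals decrease monotonically on convex targets", {
  base <- ico(3)
  tgt <- ico(4)
  for (scale in list(c(1, 1, 1), c(2, 1, 1))) {
    f <- fit_surface(list(vertices = tgt$vertices %*% diag(scale),
                          faces = tgt$faces),
                     3 * base$vertices, base$faces,
                     warn_not_enclosing = FALSE)
    expect_true(all(diff(f$history$mean) <= 1e-9))
  }
})

test_that("fitting a converged frame again barely moves it", {
  base <- ico(3)
  tgt <- list(vertices = ico(4)$vertices, faces = ico(4)$faces)
  f1 <- fit_surface(tgt, 2 * base$vertices, base$faces,
                    warn_not_enclosing = FALSE)
  f2 <- fit_surface(tgt, f1$vertices, base$faces,
                    warn_not_enclosing = FALSE)
  expect_lt(max(sqrt(rowSums((f2$vertices - f1$vertices)^2))), f2$tol)
})

test_that("a non-enclosing start warns but still fits", {
  base <- ico(2)
  tgt <- list(vertices = ico(3)$vertices, faces = ico(3)$faces)
  expect_warning(
    f <- fit_surface(tgt, 0.5 * base$vertices, base$faces),
    "does not enclose")
  expect_true(f$converged)
})

test_that("fit rejects open targets", {
  m <- ico(1)
  open <- list(vertices = m$vertices, faces = m$faces[-1, ])
  expect_error(fit_surface(open, m$vertices, m$faces), "not closed")
})

test_that("markers are static for a static embryo and co-move rigidly", {
  base <- ico(3)
  shape <- ico(3)
  mesh <- list(vertices = 50 * shape$vertices, faces = shape$faces)
  frames <- list(mesh, mesh, mesh)
  fitted <- propagate_markers(frames, c(0, 0.1, 0.2), base)
  d12 <- max(sqrt(rowSums((frame_positions(fitted, 2) -
                           frame_positions(fitted, 1))^2)))
  d23 <- max(sqrt(rowSums((frame_positions(fitted, 3) -
                           frame_positions(fitted, 2))^2)))
  med <- median_edge_length(mesh$vertices, mesh$faces)
  expect_lt(d12, 0.5 * med)
  expect_lt(d23, 0.5 * med)

  # small rigid translation: marker displacement recovers the translation
  # up to the tangential slide inherent to distance-based tracking
  shift <- c(1.5, -1, 0.5)
  frames_t <- list(mesh,
                   list(vertices = sweep(mesh$vertices, 2, shift, "+"),
                        faces = mesh$faces),
                   list(vertices = sweep(mesh$vertices, 2, 2 * shift, "+"),
                        faces = mesh$faces))
  ft <- propagate_markers(frames_t, c(0, 0.1, 0.2), base)
  disp <- frame_positions(ft, 2) - frame_positions(ft, 1)
  expect_lt(max(abs(sweep(disp, 2, shift))), 0.5 * med)
})

test_that("markers track a slow radial pulsation radially", {
  base <- ico(3)
  sim <- make_deforming_sphere(
    default_pulsation_script(n_frames = 12, seed = 5), base)
  fitted <- propagate_markers(frames_of(sim$surface), sim$surface$times,
                              base)
  expect_identical(dim(fitted$positions)[2:3],
                   c(nrow(base$vertices), 3L))
  u_prev <- frame_positions(fitted, 1)
  u_prev <- u_prev / sqrt(rowSums(u_prev^2))
  for (k in 2:12) {
    u <- frame_positions(fitted, k)
    u <- u / sqrt(rowSums(u^2))
    drift <- acos(pmin(1, rowSums(u * u_prev)))
    expect_lt(max(drift), pi / 180)  # < 1 degree per frame
    u_prev <- u
  }
})

test_that("evolving_surface flags the large-deformation regime", {
  base <- ico(1)
  nv <- nrow(base$vertices)
  pos <- array(NA_real_, c(2, nv, 3))
  pos[1, , ] <- base$vertices
  pos[2, , ] <- base$vertices * 5  # jump far beyond one edge length
  expect_warning(evolving_surface(c(0, 1), pos, base$faces),
                 "small-deformation")
})

test_that("self-intersection scan sees crossing geometry", {
  # two interpenetrating tetrahedra
  tet <- function(ctr, s) {
    v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * s
    v <- sweep(v, 2, ctr, "+")
    f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
    storage.mode(f) <- "integer"
    list(vertices = v, faces = f)
  }
  a <- tet(c(0, 0, 0), 1)
  b <- tet(c(0.4, 0.1, 0.2), 1)
  both <- list(vertices = rbind(a$vertices, b$vertices),
               faces = rbind(a$faces, b$faces + 4L))
  expect_gt(nrow(self_intersections(both$vertices, both$faces)), 0)
  expect_identical(nrow(self_intersections(a$vertices, a$faces)), 0L)
})
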
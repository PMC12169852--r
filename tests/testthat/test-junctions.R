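test_that("three boxes meeting along an edge give one junction there", {
  cells <- list(c1 = box_mesh(c(0, 0, 0), c(1, 1, 1)),
                c2 = box_mesh(c(-1, 0, 0), c(0, 1, 1)),
                c3 = box_mesh(c(0, -1, 0), c(1, 0, 1)))
  tol <- 0.6
  det <- detect_junctions(cells, contact_tol = tol)
  expect_identical(nrow(det), 1L)
  # the shared edge is x = 0, y = 0, z in [0, 1]
  expect_lt(sqrt(det$x[1]^2 + det$y[1]^2), tol)
  expect_setequal(attr(det, "members")[[det$id[1]]], c("c1", "c2", "c3"))

  # brute-force oracle: mean of all barycenters involved in mutually-near
  # triangle triples
  bary <- lapply(cells, function(cl)
    face_normals_areas(cl$vertices, cl$faces)$centroids)
  pts <- NULL
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    for (r in seq_len(nrow(bary[[i]]))) {
      p <- bary[[i]][r, ]
      near <- vapply(others, function(j)
        min(sqrt(rowSums(sweep(bary[[j]], 2, p)^2))) < tol, logical(1))
      if (all(near)) pts <- rbind(pts, p)
    }
  }
  oracle <- colMeans(pts)
  expect_lt(sqrt(sum((c(det$x[1], det$y[1], det$z[1]) - oracle)^2)), tol)
})

test_that("fewer than three cells yield no junctions", {
  cells <- list(c1 = box_mesh(c(0, 0, 0), c(1, 1, 1)),
                c2 = box_mesh(c(-1, 0, 0), c(0, 1, 1)))
  expect_identical(nrow(detect_junctions(cells)), 0L)
})

test_that("separated cells yield no junctions", {
  cells <- list(c1 = box_mesh(c(0, 0, 0), c(1, 1, 1)),
                c2 = box_mesh(c(5, 0, 0), c(6, 1, 1)),
                c3 = box_mesh(c(0, 5, 0), c(1, 6, 1)))
  expect_identical(nrow(detect_junctions(cells, contact_tol = 0.5)), 0L)
})

test_that("tessellation junctions are recovered from the cell meshes", {
  m <- ico(3)
  tess <- make_cell_tessellation(60 * m$vertices, m$faces, 12, seed = 9)
  det <- detect_junctions(tess$cells)
  tol <- 1.5 * morphospectra:::pooled_median_edge(tess$cells)
  tp <- as.matrix(tess$junctions[, c("x", "y", "z")])
  dp <- as.matrix(det[, c("x", "y", "z")])
  d2 <- outer(rowSums(tp^2), rowSums(dp^2), "+") - 2 * tcrossprod(tp, dp)
  recovery <- mean(sqrt(pmax(apply(d2, 1, min), 0)) < tol)
  expect_gte(recovery, 0.9)
  expect_true(all(det$n_members >= 3))
})

test_that("junction error vanishes for static embryos and stays in the
           Lagrangian regime for small rigid translations", {
  base <- ico(3)
  m <- list(vertices = 60 * ico(3)$vertices, faces = ico(3)$faces)
  tess <- make_cell_tessellation(m$vertices, m$faces, 10, seed = 2)
  times <- c(0, 0.1, 0.2)

  run_case <- function(frames) {
    fitted <- propagate_markers(frames, times, base)
    dets <- lapply(frames, function(fr)
      detect_junctions(cells_at_frame(tess, fr$vertices, fr$faces)))
    tracks <- junction_tracks(dets, times)
    junction_displacement_error(tracks, fitted,
                                apex_edge_length(tess$cells))
  }

  err_static <- run_case(list(m, m, m))
  expect_lt(max(err_static$series$mean_error), 1e-9)

  # tangential motion of a sphere is invisible to surface-distance
  # fitting (a translated sphere is the same point set), so co-movement
  # is only approximate; for a small per-frame step the error must stay
  # within the Lagrangian-regime bound
  shift <- c(0.4, 0.1, -0.2)
  frames_t <- list(m,
                   list(vertices = sweep(m$vertices, 2, shift, "+"),
                        faces = m$faces),
                   list(vertices = sweep(m$vertices, 2, 2 * shift, "+"),
                        faces = m$faces))
  err_rigid <- run_case(frames_t)
  expect_lt(max(err_rigid$series$mean_error), 0.08)
})

test_that("junctions with fewer than two frames are skipped", {
  base <- ico(2)
  nv <- nrow(base$vertices)
  pos <- array(rep(base$vertices, each = 3), c(3, nv, 3))
  fitted <- evolving_surface(c(0, 1, 2), pos, base$faces)
  tracks <- list(j1 = list(id = "j1", members = c("a", "b", "c"),
                           positions = rbind(c(1, 0, 0),
                                             matrix(NA, 2, 3))))
  res <- junction_displacement_error(tracks, fitted, apex_edge = 1)
  expect_true(all(is.na(res$per_junction)))
  expect_true(all(res$series$n_junctions == 0))
})
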
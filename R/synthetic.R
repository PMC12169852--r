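# Ground-truthed synthetic embryos: a deforming genus-0 surface driven by
# real spherical-harmonic radial modes, global pulses (synchronized-
# division analogue) and polar indentation (invagination analogue), plus a
# spherical centroidal Voronoi cell tessellation with known 3-cell
# junctions. Everything is deterministic given the script and seed.

#' Deformation script for the synthetic embryo
#'
#' Describes a radius field over the reference sphere,
#' `R(theta, phi, t) = R0 (1 + g(t) + sum a_lm(t) Yr_lm + pulses(t))`,
#' where `Yr` are real orthonormal spherical harmonics, `g` an optional
#' global amplitude, and each pulse a Gaussian bump in time shared by the
#' whole surface. Defaults mimic densely sampled time-lapse recordings of
#' early embryos: radius 60 length units (microns for typical ascidian
#' data), 60 frames 2 minutes apart, deformations small between frames.
#'
#' @param n_frames Number of frames.
#' @param dt Frame spacing, hours.
#' @param R0 Rest radius, length units.
#' @param radial_modes List of `list(l =, m =, amplitude = function(t))`
#'   entries (dimensionless amplitudes of real harmonics).
#' @param pulse_schedule Data frame with columns `t_center`, `width`,
#'   `amplitude`: global Gaussian pulses `A exp(-(t - tc)^2 / (2 w^2))`.
#' @param global_amplitude Optional `function(t)` added uniformly.
#' @param noise_sigma Isotropic Gaussian vertex jitter, length units,
#'   applied after the deformation (0 = noise-free).
#' @param seed Integer seed for the jitter.
#' @return Object of class `deformation_script`.
#' @export
deformation_script <- function(n_frames = 60L, dt = 1 / 30, R0 = 60,
                               radial_modes = list(),
                               pulse_schedule = NULL,
                               global_amplitude = NULL,
                               noise_sigma = 0, seed = 1L) {
  stopifnot(n_frames >= 1, dt > 0, R0 > 0, noise_sigma >= 0)
  for (md in radial_modes)
    stopifnot(is.numeric(md$l), is.numeric(md$m), abs(md$m) <= md$l,
              is.function(md$amplitude))
  if (!is.null(pulse_schedule))
    stopifnot(all(c("t_center", "width", "amplitude") %in%
                  names(pulse_schedule)), all(pulse_schedule$width > 0))
  structure(list(n_frames = as.integer(n_frames), dt = dt, R0 = R0,
                 radial_modes = radial_modes,
                 pulse_schedule = pulse_schedule,
                 global_amplitude = global_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "deformation_script")
}

#' Default radial-pulsation script
#'
#' A slow global pulsation `R(t) = R0 (1 + 0.05 sin(2 pi t))` (5% radius
#' amplitude, 1-hour period) sampled every 2 minutes for 2 hours: the
#' small-deformation regime the marker scheme is designed for.
#'
#' @param ... Overrides passed to [deformation_script()].
#' @export
default_pulsation_script <- function(...) {
  deformation_script(global_amplitude = function(t) 0.05 * sin(2 * pi * t),
                     ...)
}

script_radius_fun <- function(script, base) {
  Yr <- NULL
  if (length(script$radial_modes)) {
    lmax <- max(vapply(script$radial_modes, `[[`, numeric(1), "l"))
    Yr <- sh_real_basis(base$theta, base$phi, lmax)
  }
  nv <- nrow(base$vertices)
  function(t) {
    rel <- rep(1, nv)
    if (!is.null(script$global_amplitude))
      rel <- rel + script$global_amplitude(t)
    for (md in script$radial_modes)
      rel <- rel + md$amplitude(t) * Yr[, sh_index(md$l, md$m)]
    ps <- script$pulse_schedule
    if (!is.null(ps))
      for (r in seq_len(nrow(ps)))
        rel <- rel + ps$amplitude[r] *
          exp(-(t - ps$t_center[r])^2 / (2 * ps$width[r]^2))
    script$R0 * rel
  }
}

synthesize_surface <- function(radius_fun, base, times, noise_sigma, seed) {
  nv <- nrow(base$vertices)
  nt <- length(times)
  positions <- array(NA_real_, c(nt, nv, 3))
  for (k in seq_len(nt)) {
    r <- radius_fun(times[k])
    if (any(r <= 0))
      stopf("script error: non-positive radius at t = %.4g", times[k])
    positions[k, , ] <- base$vertices * r
  }
  trajectories <- positions
  if (noise_sigma > 0) {
    jitter <- with_seed(seed, array(rnorm(length(positions), sd = noise_sigma),
                                    dim(positions)))
    positions <- positions + jitter
  }
  h <- 1e-6
  velocities <- array(NA_real_, c(nt, nv, 3))
  for (k in seq_len(nt)) {
    rdot <- (radius_fun(times[k] + h) - radius_fun(times[k] - h)) / (2 * h)
    velocities[k, , ] <- base$vertices * rdot
  }
  list(positions = positions, trajectories = trajectories,
       velocities = velocities)
}

#' Generate a deforming sphere with ground truth
#'
#' Realizes a [deformation_script()] on the reference sphere mesh. Vertex
#' `v` at time `t` sits at `R(theta_v, phi_v, t)` times its unit
#' direction, so the exact particle trajectories and analytic radial
#' velocities are known.
#'
#' @param script A `deformation_script`.
#' @param base A [build_icosphere()] mesh.
#' @return List with `surface` (an `evolving_surface`, provenance
#'   `"raw_input"`) and `truth`: `trajectories` (noise-free vertex paths),
#'   `velocities` (analytic, per frame), `modes` (data frame of driven
#'   `(l, m)`), `event_times` (pulse centers), `radius_fun`.
#' @export
make_deforming_sphere <- function(script, base) {
  stopifnot(inherits(script, "deformation_script"),
            inherits(base, "sphere_mesh"))
  times <- (seq_len(script$n_frames) - 1L) * script$dt
  rf <- script_radius_fun(script, base)
  syn <- synthesize_surface(rf, base, times, script$noise_sigma,
                            script$seed)
  modes <- if (length(script$radial_modes)) {
    data.frame(l = vapply(script$radial_modes, `[[`, numeric(1), "l"),
               m = vapply(script$radial_modes, `[[`, numeric(1), "m"))
  } else data.frame(l = numeric(0), m = numeric(0))
  list(surface = evolving_surface(times, syn$positions, base$faces,
                                  provenance = "raw_input"),
       truth = list(trajectories = syn$trajectories,
                    velocities = syn$velocities, modes = modes,
                    event_times = script$pulse_schedule$t_center,
                    radius_fun = rf))
}

#' Two-phase smooth depth schedule
#'
#' Sum of two smooth (tanh) steps: depth ramps around `c1`, plateaus, then
#' ramps again around `c2`. The depth rate peaks exactly at `c1` and `c2`,
#' which the returned function exposes via attribute `"ramp_centers"`.
#'
#' @param d1,d2 Step depths, length units.
#' @param c1,c2 Ramp center times, hours.
#' @param w1,w2 Ramp widths (tanh time constants), hours.
#' @export
two_phase_depth <- function(d1, c1, w1, d2, c2, w2) {
  f <- function(t) d1 / 2 * (1 + tanh((t - c1) / w1)) +
    d2 / 2 * (1 + tanh((t - c2) / w2))
  attr(f, "ramp_centers") <- c(c1, c2)
  f
}

#' Generate an invaginating embryo with ground truth
#'
#' A smooth polar cap around the south pole (the vegetal-pole analogue) is
#' displaced inward by `depth(t)` with C1 blending at the cap rim:
#' `R = R0 - depth(t) B(s)` with `B(s) = (1 - s^2)^2`, `s` the normalized
#' angle from the pole. The surface stays a radial graph over the sphere,
#' hence embedded and genus 0, for any `depth < R0`.
#'
#' @param depth `function(t)` giving the indentation depth, length units.
#' @param cap_angle Angular cap radius, radians, in `(0, pi/2)`.
#' @param n_frames,dt,R0 As in [deformation_script()].
#' @param base A [build_icosphere()] mesh.
#' @return As [make_deforming_sphere()]; `truth$event_times` are the local
#'   maxima of the depth rate (the ramp centers for a two-phase schedule),
#'   and `truth$cap_vertices` indexes the vertices inside the cap.
#' @export
make_invagination_embryo <- function(depth, cap_angle = pi / 4,
                                     n_frames = 60L, dt = 1 / 30, R0 = 60,
                                     base) {
  stopifnot(is.function(depth), cap_angle > 0, cap_angle < pi / 2)
  times <- (seq_len(n_frames) - 1L) * dt
  if (max(vapply(times, depth, numeric(1))) >= R0)
    stopf("script error: depth reaches the embryo center (self-intersecting schedule)")
  s <- (pi - base$theta) / cap_angle
  B <- ifelse(s < 1, (1 - s^2)^2, 0)
  rf <- function(t) R0 - depth(t) * B
  syn <- synthesize_surface(rf, base, times, noise_sigma = 0, seed = 1L)
  events <- attr(depth, "ramp_centers")
  if (is.null(events)) {
    tf <- seq(times[1], times[length(times)], length.out = 20L * n_frames)
    h <- 1e-6
    rate <- abs(vapply(tf, function(t)
      (depth(t + h) - depth(t - h)) / (2 * h), numeric(1)))
    pk <- which(diff(sign(diff(rate))) == -2) + 1L
    events <- tf[pk[rate[pk] > 0.1 * max(rate)]]
  }
  list(surface = evolving_surface(times, syn$positions, base$faces,
                                  provenance = "raw_input"),
       truth = list(trajectories = syn$trajectories,
                    velocities = syn$velocities,
                    event_times = events, radius_fun = rf,
                    cap_vertices = which(B > 0)))
}

# ---------------------------------------------------------------------------
# spherical centroidal Voronoi tessellation into cells

#' Tessellate a closed surface into cells with known junctions
#'
#' Seeds `n_cells` directions (seeded RNG), runs Lloyd iterations of a
#' spherical centroidal Voronoi tessellation on the vertex directions,
#' assigns faces to cells by centroid, and extrudes each patch inward into
#' a closed cell mesh. The true 3-cell junction points are the mesh
#' vertices where three or more cell patches meet, labeled by their
#' member-cell sets.
#'
#' @param vertices,faces One frame of a closed genus-0 surface.
#' @param n_cells Number of cells (`>= 3`, at most `n_vertices / 10`).
#' @param seed Integer seed for the Voronoi seeds.
#' @param thickness Inward extrusion depth; default 8% of the mean radius.
#' @param lloyd_iter Lloyd relaxation iterations.
#' @return Object of class `cell_tessellation`: `cells` (named list of
#'   closed meshes with `vertices`, `faces`, `apical` outer-face indices,
#'   `face_ids` into the parent surface), `assignment` (face to cell),
#'   `junctions` (data frame `id`, `x`, `y`, `z`, `n_members`, vertex
#'   index `vertex`; member sets in attribute `"members"`), `seeds`,
#'   `thickness`.
#' @export
make_cell_tessellation <- function(vertices, faces, n_cells, seed = 1L,
                                   thickness = NULL, lloyd_iter = 30L) {
  nv <- nrow(vertices)
  if (n_cells < 3L) stopf("n_cells must be >= 3")
  if (n_cells > nv / 10) stopf("n_cells > n_vertices / 10: patches under-resolved")
  ctr <- colMeans(vertices)
  vc <- sweep(vertices, 2, ctr)
  rad <- sqrt(rowSums(vc^2))
  u <- vc / rad
  seeds <- with_seed(seed, {
    s <- matrix(rnorm(3 * n_cells), n_cells, 3)
    s / sqrt(rowSums(s^2))
  })
  fa <- face_normals_areas(vertices, faces)
  w <- vertex_area_weights(list(vertices = vertices, faces = faces))
  for (it in seq_len(lloyd_iter)) {
    lab <- max.col(u %*% t(seeds), ties.method = "first")
    for (cc in seq_len(n_cells)) {
      at <- lab == cc
      if (!any(at)) {
        # dead cell: reseed at the vertex farthest from all live seeds
        far <- which.min(apply(u %*% t(seeds), 1, max))
        seeds[cc, ] <- u[far, ]
        next
      }
      m <- colSums(u[at, , drop = FALSE] * w[at])
      seeds[cc, ] <- m / sqrt(sum(m^2))
    }
  }
  face_lab <- max.col((fa$centroids - matrix(ctr, nrow(faces), 3,
                                             byrow = TRUE)) %*% t(seeds),
                      ties.method = "first")
  face_lab <- connectify_patches(faces, face_lab, n_cells)
  thickness <- thickness %||% (0.08 * mean(rad))
  nrm <- vertex_normals(vertices, faces)
  cells <- stats::setNames(vector("list", n_cells),
                           sprintf("c%02d", seq_len(n_cells)))
  for (cc in seq_len(n_cells)) {
    fid <- which(face_lab == cc)
    cells[[cc]] <- extrude_patch(vertices, faces, fid, nrm, thickness)
  }
  junctions <- true_junctions(vertices, faces, face_lab, names(cells))
  structure(list(cells = cells, assignment = face_lab,
                 junctions = junctions, seeds = seeds,
                 thickness = thickness, center = ctr),
            class = "cell_tessellation")
}

# reassign disconnected minor components of each patch to a neighbor cell
connectify_patches <- function(faces, face_lab, n_cells) {
  nf <- nrow(faces)
  # face adjacency across shared edges
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(nf), 3L)
  pairs <- split(fid, key)
  adj <- matrix(unlist(pairs[lengths(pairs) == 2L]), ncol = 2, byrow = TRUE)
  for (pass in 1:5) {
    changed <- FALSE
    for (cc in seq_len(n_cells)) {
      at <- which(face_lab == cc)
      if (length(at) < 2L) next
      sub <- adj[face_lab[adj[, 1]] == cc & face_lab[adj[, 2]] == cc, ,
                 drop = FALSE]
      comp <- components_from_edges(at, sub)
      if (length(comp) <= 1L) next
      sizes <- lengths(comp)
      keep <- which.max(sizes)
      for (q in seq_along(comp)) {
        if (q == keep) next
        for (f in comp[[q]]) {
          nb <- c(adj[adj[, 1] == f, 2], adj[adj[, 2] == f, 1])
          nb_lab <- face_lab[nb]
          nb_lab <- nb_lab[nb_lab != cc]
          if (length(nb_lab)) {
            face_lab[f] <- as.integer(names(which.max(table(nb_lab))))
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  face_lab
}

components_from_edges <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) {
      parent[[as.character(x)]] <<- parent[[as.character(
        parent[[as.character(x)]])]]
      x <- parent[[as.character(x)]]
    }
    x
  }
  if (nrow(edges))
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1])
      b <- find(edges[r, 2])
      if (a != b) parent[[as.character(a)]] <- b
    }
  roots <- vapply(nodes, find, numeric(1))
  unname(split(nodes, roots))
}

# closed prism: outer patch + inward offset copy + boundary walls
extrude_patch <- function(vertices, faces, fid, normals, thickness) {
  sub <- faces[fid, , drop = FALSE]
  vs <- sort(unique(as.vector(sub)))
  remap <- integer(max(vs))
  remap[vs] <- seq_along(vs)
  outer_v <- vertices[vs, , drop = FALSE]
  inner_v <- outer_v - thickness * normals[vs, , drop = FALSE]
  outer_f <- matrix(remap[sub], ncol = 3)
  nvo <- length(vs)
  inner_f <- outer_f[, c(1, 3, 2)] + nvo
  # directed boundary edges (present once in the patch)
  dir_e <- rbind(outer_f[, c(1, 2)], outer_f[, c(2, 3)], outer_f[, c(3, 1)])
  key <- paste(dir_e[, 1], dir_e[, 2])
  rkey <- paste(dir_e[, 2], dir_e[, 1])
  bnd <- dir_e[!(key %in% rkey), , drop = FALSE]
  walls <- rbind(cbind(bnd[, 2], bnd[, 1], bnd[, 1] + nvo),
                 cbind(bnd[, 2], bnd[, 1] + nvo, bnd[, 2] + nvo))
  f <- rbind(outer_f, inner_f, walls)
  storage.mode(f) <- "integer"
  list(vertices = rbind(outer_v, inner_v), faces = f,
       apical = seq_len(nrow(outer_f)), face_ids = fid,
       vertex_ids = vs)
}

# mesh vertices whose incident faces span >= 3 cells, clustered by member
# set and adjacency (the same 3 cells can meet at several distinct points)
true_junctions <- function(vertices, faces, face_lab, cell_names) {
  nv <- nrow(vertices)
  inc <- split(rep(face_lab, 3L), as.vector(faces))
  members <- lapply(inc, function(x) sort(unique(x)))
  vs <- as.integer(names(members))[lengths(members) >= 3L]
  if (!length(vs)) {
    out <- data.frame(id = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), n_members = integer(0),
                      vertex = integer(0))
    attr(out, "members") <- list()
    return(out)
  }
  mem <- members[as.character(vs)]
  keys <- vapply(mem, function(m)
    paste(cell_names[m], collapse = "+"), character(1))
  e <- mesh_edges(faces)
  rows <- list()
  mems <- list()
  for (key in unique(keys)) {
    grp <- vs[keys == key]
    sube <- e[e[, 1] %in% grp & e[, 2] %in% grp, , drop = FALSE]
    comp <- components_from_edges(grp, sube)
    for (q in seq_along(comp)) {
      id <- if (length(comp) > 1L) paste0(key, "#", q) else key
      pos <- colMeans(vertices[comp[[q]], , drop = FALSE])
      rows[[length(rows) + 1L]] <-
        data.frame(id = id, x = pos[1], y = pos[2], z = pos[3],
                   n_members = length(mem[[match(comp[[q]][1], vs)]]),
                   vertex = comp[[q]][1])
      mems[[id]] <- cell_names[mem[[match(comp[[q]][1], vs)]]]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- mems
  out
}

#' Rebuild the tessellation's cell meshes on another frame
#'
#' The tessellation is Lagrangian: face-to-cell assignment is fixed, so the
#' cells of any frame of an evolving surface follow by re-extruding the
#' same patches at that frame's vertex positions.
#'
#' @param tess A `cell_tessellation`.
#' @param vertices Vertex positions of the new frame (same connectivity).
#' @param faces The shared face array.
#' @return Named list of cell meshes, as in [make_cell_tessellation()].
#' @export
cells_at_frame <- function(tess, vertices, faces) {
  nrm <- vertex_normals(vertices, faces)
  lapply(tess$cells, function(cl)
    extrude_patch(vertices, faces, cl$face_ids, nrm, tess$thickness))
}
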
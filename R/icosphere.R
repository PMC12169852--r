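# Reference sphere mesh: an icosahedron refined by interpolating butterfly
# subdivision, re-projected to the unit sphere. Its fixed connectivity and
# per-vertex (theta, phi) parametrization are shared by every later stage.

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12,  6), c(1,  6,  2), c(1,  2,  8), c(1,  8, 11), c(1, 11, 12),
    c(2,  6, 10), c(6, 12,  5), c(12, 11, 3), c(11,  8,  7), c(8,  2,  9),
    c(4, 10,  5), c(4,  5,  3), c(4,  3,  7), c(4,  7,  9), c(4,  9, 10),
    c(5, 10,  6), c(3,  5, 12), c(7,  3, 11), c(9,  7,  8), c(10, 9,  2))
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

# ring of neighbors around vertex `a`, in rotational order starting from
# `from`, using consistently oriented faces
ordered_ring <- function(faces, a, from) {
  rows <- which(faces[, 1] == a | faces[, 2] == a | faces[, 3] == a)
  succ <- integer(0)
  keys <- integer(0)
  for (r in rows) {
    f <- faces[r, ]
    i <- which(f == a)
    x <- f[(i %% 3) + 1]
    y <- f[((i + 1) %% 3) + 1]
    keys <- c(keys, x)
    succ <- c(succ, y)
  }
  k <- length(rows)
  ring <- integer(k)
  ring[1] <- from
  for (j in 2:k) ring[j] <- succ[match(ring[j - 1], keys)]
  ring
}

# Zorin extraordinary-vertex stencil weights for valence k (edge midpoint
# adjacent to one irregular vertex); neighbor 0 is the edge's far endpoint
butterfly_irregular_weights <- function(k) {
  if (k == 3) c(5 / 12, -1 / 12, -1 / 12)
  else if (k == 4) c(3 / 8, 0, -1 / 8, 0)
  else {
    j <- 0:(k - 1)
    (0.25 + cos(2 * pi * j / k) + 0.5 * cos(4 * pi * j / k)) / k
  }
}

# one butterfly subdivision step (tension w = 1/16 on regular edges)
butterfly_subdivide <- function(vertices, faces) {
  nv <- nrow(vertices)
  edges <- mesh_edges(faces)
  ne <- nrow(edges)
  K <- nv + 1
  ekey <- function(i, j) pmin(i, j) * K + pmax(i, j)
  edge_keys <- edges[, 1] * K + edges[, 2]

  # per-edge adjacent faces and their opposite vertices
  occ_key <- c(ekey(faces[, 1], faces[, 2]),
               ekey(faces[, 2], faces[, 3]),
               ekey(faces[, 3], faces[, 1]))
  occ_opp <- c(faces[, 3], faces[, 1], faces[, 2])
  eidx <- match(occ_key, edge_keys)
  opp <- matrix(NA_integer_, ne, 2)
  first <- !duplicated(eidx)
  opp[eidx[first], 1] <- occ_opp[first]
  opp[eidx[!first], 2] <- occ_opp[!first]
  if (anyNA(opp)) stopf("butterfly subdivision requires a closed mesh")

  valence <- tabulate(as.integer(edges), nbins = nv)
  p <- edges[, 1]
  q <- edges[, 2]
  cc <- opp[, 1]
  dd <- opp[, 2]

  # wing vertex across edge (u, w), excluding known opposite `excl`
  wing <- function(u, w, excl) {
    e <- match(ekey(u, w), edge_keys)
    o1 <- opp[e, 1]
    o2 <- opp[e, 2]
    ifelse(o1 == excl, o2, o1)
  }
  w1 <- wing(p, cc, q)
  w2 <- wing(q, cc, p)
  w3 <- wing(p, dd, q)
  w4 <- wing(q, dd, p)

  reg <- valence[p] == 6L & valence[q] == 6L
  mid <- 0.5 * (vertices[p, , drop = FALSE] + vertices[q, , drop = FALSE]) +
    (1 / 8) * (vertices[cc, , drop = FALSE] + vertices[dd, , drop = FALSE]) -
    (1 / 16) * (vertices[w1, , drop = FALSE] + vertices[w2, , drop = FALSE] +
                vertices[w3, , drop = FALSE] + vertices[w4, , drop = FALSE])

  irr_point <- function(a, b) {
    k <- valence[a]
    ring <- ordered_ring(faces, a, b)
    s <- butterfly_irregular_weights(k)
    0.75 * vertices[a, ] + as.vector(s %*% vertices[ring, , drop = FALSE])
  }
  for (e in which(!reg)) {
    pa <- p[e]
    qa <- q[e]
    irr_p <- valence[pa] != 6L
    irr_q <- valence[qa] != 6L
    if (irr_p && irr_q) {
      mid[e, ] <- 0.5 * (irr_point(pa, qa) + irr_point(qa, pa))
    } else if (irr_p) {
      mid[e, ] <- irr_point(pa, qa)
    } else {
      mid[e, ] <- irr_point(qa, pa)
    }
  }

  new_v <- rbind(vertices, mid)
  m_ab <- nv + match(ekey(faces[, 1], faces[, 2]), edge_keys)
  m_bc <- nv + match(ekey(faces[, 2], faces[, 3]), edge_keys)
  m_ca <- nv + match(ekey(faces[, 3], faces[, 1]), edge_keys)
  new_f <- rbind(cbind(faces[, 1], m_ab, m_ca),
                 cbind(faces[, 2], m_bc, m_ab),
                 cbind(faces[, 3], m_ca, m_bc),
                 cbind(m_ab, m_bc, m_ca))
  dimnames(new_f) <- NULL
  storage.mode(new_f) <- "integer"
  list(vertices = new_v, faces = new_f)
}

#' Build the reference icosphere
#'
#' Constructs the fixed-topology sphere mesh shared by all pipeline stages:
#' an icosahedron refined by `subdivisions` rounds of interpolating
#' butterfly subdivision (tension 1/16 on regular edges, the
#' extraordinary-vertex stencil at the twelve valence-5 vertices), with
#' every new vertex re-projected onto the unit sphere. Connectivity is
#' deterministic: the same `subdivisions` always yields identical index
#' arrays.
#'
#' @param subdivisions Non-negative integer number of subdivision rounds
#'   (level 0 is the icosahedron: 12 vertices, 20 faces). Capped at 7.
#' @return An object of class `sphere_mesh`: a list with `vertices`
#'   (unit-norm n x 3 matrix), `faces`, `edges`, `theta` (polar angle from
#'   +z, radians), `phi` (azimuth in `[0, 2*pi)`), `subdivision_level`.
#' @examples
#' m <- build_icosphere(2)
#' nrow(m$vertices)  # 162
#' @export
build_icosphere <- function(subdivisions) {
  if (length(subdivisions) != 1L || is.na(subdivisions) ||
      subdivisions != round(subdivisions) || subdivisions < 0)
    stopf("subdivisions must be a single non-negative integer")
  if (subdivisions > 7)
    stopf("subdivisions capped at 7 (memory); got %d", subdivisions)
  m <- icosahedron()
  lvl <- 0L
  while (lvl < subdivisions) {
    m <- butterfly_subdivide(m$vertices, m$faces)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
    lvl <- lvl + 1L
  }
  ang <- spherical_coords_of(m$vertices)
  structure(list(vertices = m$vertices,
                 faces = m$faces,
                 edges = mesh_edges(m$faces),
                 theta = ang$theta,
                 phi = ang$phi,
                 subdivision_level = as.integer(subdivisions)),
            class = "sphere_mesh")
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat(sprintf("<sphere_mesh> level %d: %d vertices, %d edges, %d faces\n",
              x$subdivision_level, nrow(x$vertices), nrow(x$edges),
              nrow(x$faces)))
  invisible(x)
}

spherical_coords_of <- function(vertices) {
  z <- pmin(pmax(vertices[, 3], -1), 1)
  theta <- acos(z)
  phi <- atan2(vertices[, 2], vertices[, 1]) %% (2 * pi)
  list(theta = theta, phi = phi)
}

#' Spherical coordinates of unit-sphere vertices
#'
#' Polar angle `theta = acos(z)` in `[0, pi]` (measured from +z) and
#' azimuth `phi = atan2(y, x)` wrapped into `[0, 2*pi)`. The inverse map
#' `sph_to_cart()` reconstructs the vertices to machine precision.
#'
#' @param mesh A `sphere_mesh`, or an n x 3 matrix of unit vectors.
#' @param tol Maximum allowed deviation of vertex norms from 1.
#' @return List with numeric vectors `theta` and `phi`.
#' @export
spherical_coords <- function(mesh, tol = 1e-8) {
  v <- if (inherits(mesh, "sphere_mesh")) mesh$vertices else mesh
  dev <- abs(sqrt(rowSums(v^2)) - 1)
  if (any(dev > tol))
    stopf("vertex off the unit sphere: max |norm - 1| = %.3g (tol %.3g)",
          max(dev), tol)
  spherical_coords_of(v)
}

#' Cartesian coordinates from spherical angles
#' @param theta Polar angle(s), radians in `[0, pi]`.
#' @param phi Azimuth(s), radians.
#' @return n x 3 matrix of unit vectors.
#' @export
sph_to_cart <- function(theta, phi) {
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Barycentric vertex area weights
#'
#' One-third lumping of incident triangle areas onto vertices: the standard
#' quadrature weights for surface integrals sampled at vertices. Weights sum
#' to the total (polyhedral) surface area.
#'
#' @param mesh A `sphere_mesh`, or a list with `vertices` and `faces`.
#' @return Numeric vector of per-vertex areas (squared length units).
#' @export
vertex_area_weights <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  validate_closed_mesh(v, f, "vertex_area_weights input")
  fa <- face_normals_areas(v, f)
  areas <- fa$areas
  if (any(areas == 0)) {
    warnf("%d degenerate (zero-area) triangle(s): contributing zero weight",
          sum(areas == 0))
  }
  w <- numeric(nrow(v))
  third <- areas / 3
  for (k in 1:3)
    w <- w + tapply_sum(f[, k], third, nrow(v))
  w
}
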
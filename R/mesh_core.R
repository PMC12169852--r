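# Shared triangle-mesh helpers used by every module: edge extraction,
# areas, normals, manifold checks, ring neighborhoods. Faces are 1-based
# integer triples; vertices are an n x 3 numeric matrix.

#' Unique undirected edges of a triangle mesh
#'
#' @param faces Integer matrix (n_faces x 3) of 1-based vertex indices.
#' @return Integer matrix (n_edges x 2), each row sorted, rows unique and
#'   ordered lexicographically (deterministic).
#' @export
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# counts of incident faces per undirected edge (for manifold checks)
edge_face_counts <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Check that a mesh is a closed 2-manifold surface
#'
#' Every edge must be shared by exactly two faces. Returns a list with
#' `closed` (logical), `n_boundary_edges` and `n_nonmanifold_edges`.
#'
#' @inheritParams mesh_edges
#' @export
is_closed_mesh <- function(faces) {
  cnt <- edge_face_counts(faces)
  list(closed = all(cnt == 2L),
       n_boundary_edges = sum(cnt == 1L),
       n_nonmanifold_edges = sum(cnt > 2L))
}

validate_closed_mesh <- function(vertices, faces, what = "mesh") {
  if (!is.matrix(vertices) || ncol(vertices) != 3)
    stopf("%s: vertices must be an n x 3 matrix", what)
  if (!is.matrix(faces) || ncol(faces) != 3)
    stopf("%s: faces must be an n x 3 index matrix", what)
  if (nrow(vertices) < 4L || nrow(faces) < 4L)
    stopf("%s: too few vertices/faces for a closed surface", what)
  if (max(faces) > nrow(vertices) || min(faces) < 1L)
    stopf("%s: face indices out of range", what)
  chk <- is_closed_mesh(faces)
  if (!chk$closed)
    stopf("%s is not closed: %d boundary edge(s), %d non-manifold edge(s)",
          what, chk$n_boundary_edges, chk$n_nonmanifold_edges)
  invisible(TRUE)
}

#' Per-face unit normals and areas
#'
#' @param vertices Numeric matrix (n_vertices x 3).
#' @param faces Integer matrix (n_faces x 3).
#' @return List with `normals` (n_faces x 3, unit where non-degenerate),
#'   `areas` (n_faces), `centroids` (n_faces x 3).
#' @export
face_normals_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  areas <- len / 2
  unit <- n
  ok <- len > 0
  unit[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  list(normals = unit, areas = areas, centroids = (a + b + c) / 3)
}

#' Area-weighted outward vertex normals
#'
#' @inheritParams face_normals_areas
#' @return n_vertices x 3 matrix of unit normals.
#' @export
vertex_normals <- function(vertices, faces) {
  fn <- face_normals_areas(vertices, faces)
  nv <- nrow(vertices)
  acc <- matrix(0, nv, 3)
  w <- fn$areas
  for (k in 1:3) {
    idx <- faces[, k]
    for (d in 1:3)
      acc[, d] <- acc[, d] + tapply_sum(idx, fn$normals[, d] * w, nv)
  }
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  acc / len
}

# fast grouped sum onto 1..n (base tapply is slow for this hot path)
tapply_sum <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Median edge length of a mesh
#' @inheritParams face_normals_areas
#' @export
median_edge_length <- function(vertices, faces) {
  e <- mesh_edges(faces)
  stats::median(sqrt(rowSums((vertices[e[, 1], , drop = FALSE] -
                              vertices[e[, 2], , drop = FALSE])^2)))
}

#' First- and second-order ring neighborhoods
#'
#' For each vertex, the indices of its 1-ring (edge-adjacent) and 2-ring
#' (neighbors-of-neighbors, excluding the vertex and its 1-ring) neighbors.
#' Depends on connectivity only, so it is computed once per mesh topology.
#'
#' @inheritParams mesh_edges
#' @param n_vertices Number of vertices.
#' @return List with elements `ring1` and `ring2`, each a list of integer
#'   vectors.
#' @export
ring_neighbors <- function(faces, n_vertices) {
  e <- mesh_edges(faces)
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  ring1 <- vector("list", n_vertices)
  ring1[as.integer(names(adj))] <- lapply(adj, function(x) sort(unique(x)))
  ring2 <- vector("list", n_vertices)
  for (v in seq_len(n_vertices)) {
    r1 <- ring1[[v]]
    if (is.null(r1)) {
      ring1[[v]] <- integer(0)
      ring2[[v]] <- integer(0)
      next
    }
    r2 <- unique(unlist(ring1[r1], use.names = FALSE))
    ring2[[v]] <- sort(setdiff(r2, c(v, r1)))
  }
  list(ring1 = ring1, ring2 = ring2)
}

#' Scan a mesh for self-intersecting triangle pairs
#'
#' Exact triangle-triangle intersection test over all non-adjacent face
#' pairs (axis-aligned bounding boxes prune the search). Coplanar contacts
#' are not reported. Intended for moderate mesh sizes.
#'
#' @inheritParams face_normals_areas
#' @param max_pairs Stop after this many intersecting pairs.
#' @return Integer matrix (k x 2) of intersecting face index pairs.
#' @export
self_intersections <- function(vertices, faces, max_pairs = 1000L) {
  storage.mode(faces) <- "integer"
  cpp_self_intersections(vertices, faces, max_pairs)
}
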
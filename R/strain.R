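# Surface strain-rate kinematics: marker velocities, the symmetric part of
# the intrinsic (tangential) velocity gradient on the triangle mesh, ring
# Gaussian smoothing, and the scalar strain-rate field.

#' Velocity field of an evolving surface
#'
#' Central differences in the interior, one-sided at the first and last
#' frame: `v_k = (x_{k+1} - x_{k-1}) / (t_{k+1} - t_{k-1})`.
#'
#' @param es An `evolving_surface`.
#' @return Array `[frame, vertex, 3]`, length units per hour.
#' @export
velocity_field <- function(es) {
  times <- es$times
  if (length(times) < 2L) stopf("need at least 2 frames")
  if (any(diff(times) == 0)) stopf("duplicate timestamps")
  p <- es$positions
  n <- length(times)
  v <- array(NA_real_, dim(p))
  v[1, , ] <- (p[2, , ] - p[1, , ]) / (times[2] - times[1])
  v[n, , ] <- (p[n, , ] - p[n - 1, , ]) / (times[n] - times[n - 1])
  if (n > 2L) {
    for (k in 2:(n - 1))
      v[k, , ] <- (p[k + 1, , ] - p[k - 1, , ]) / (times[k + 1] - times[k - 1])
  }
  v
}

# per-face gradients of a linear per-vertex field: for face (i,j,k) with
# unit normal N and area A, grad(hat_i) = N x (v_k - v_j) / (2A)
face_gradient_basis <- function(vertices, faces) {
  fa <- face_normals_areas(vertices, faces)
  n <- fa$normals
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  cross_rows <- function(u, w) {
    cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
          u[, 3] * w[, 1] - u[, 1] * w[, 3],
          u[, 1] * w[, 2] - u[, 2] * w[, 1])
  }
  inv2a <- ifelse(fa$areas > 0, 1 / (2 * fa$areas), 0)
  list(g1 = cross_rows(n, c - b) * inv2a,
       g2 = cross_rows(n, a - c) * inv2a,
       g3 = cross_rows(n, b - a) * inv2a,
       areas = fa$areas)
}

#' Surface strain-rate tensor for one frame
#'
#' For each velocity component, the per-triangle linear-interpolation
#' gradient (tangent to the triangle) is averaged onto vertices with area
#' weights, giving the intrinsic velocity-gradient matrix `G` (rows are the
#' tangential gradients of `v_x`, `v_y`, `v_z`). The strain-rate tensor is
#' the in-surface part of its symmetrization, `D = P sym(G) P`, with `P`
#' the projector onto the vertex tangent plane. The projection removes the
#' apparent normal-direction shear that rigid rotations would otherwise
#' leave in the 3x3 representation, so rigid motions give `D ~ 0` while a
#' uniform expansion `v = c x` on a sphere gives eigenvalues `{c, c, 0}`.
#'
#' @param vertices Frame vertex positions (n x 3).
#' @param faces Closed triangle connectivity.
#' @param velocity Per-vertex velocity (n x 3).
#' @return Array `[vertex, 3, 3]` of symmetric tensors (1/hour), with the
#'   unprojected gradient in attribute `"G"` and flagged vertices (zero
#'   incident area, tensor replaced by the ring-neighbor average) in
#'   attribute `"flagged"`.
#' @export
strain_rate_tensor <- function(vertices, faces, velocity) {
  nv <- nrow(vertices)
  stopifnot(nrow(velocity) == nv, ncol(velocity) == 3)
  gb <- face_gradient_basis(vertices, faces)
  # G[v, c, ] = area-weighted mean over incident faces of grad(velocity_c)
  w <- gb$areas
  wsum <- numeric(nv)
  for (k in 1:3) wsum <- wsum + tapply_sum(faces[, k], w, nv)
  flagged <- which(wsum == 0)
  wsum[wsum == 0] <- 1
  G <- array(0, c(nv, 3, 3))
  for (cc in 1:3) {
    fg <- gb$g1 * velocity[faces[, 1], cc] +
          gb$g2 * velocity[faces[, 2], cc] +
          gb$g3 * velocity[faces[, 3], cc]
    for (d in 1:3) {
      acc <- numeric(nv)
      for (k in 1:3)
        acc <- acc + tapply_sum(faces[, k], fg[, d] * w, nv)
      G[, cc, d] <- acc / wsum
    }
  }
  S <- (G + aperm(G, c(1, 3, 2))) / 2
  # in-surface projection: D = P S P, P = I - n n^T (vertex normal n)
  n <- vertex_normals(vertices, faces)
  a1 <- S[, 1, 1] * n[, 1] + S[, 1, 2] * n[, 2] + S[, 1, 3] * n[, 3]
  a2 <- S[, 2, 1] * n[, 1] + S[, 2, 2] * n[, 2] + S[, 2, 3] * n[, 3]
  a3 <- S[, 3, 1] * n[, 1] + S[, 3, 2] * n[, 2] + S[, 3, 3] * n[, 3]
  s <- a1 * n[, 1] + a2 * n[, 2] + a3 * n[, 3]
  a <- cbind(a1, a2, a3)
  D <- S
  for (i in 1:3)
    for (j in 1:3)
      D[, i, j] <- S[, i, j] - n[, i] * a[, j] - a[, i] * n[, j] +
        s * n[, i] * n[, j]
  if (length(flagged)) {
    rings <- ring_neighbors(faces, nv)
    for (v in flagged) {
      nb <- setdiff(rings$ring1[[v]], flagged)
      if (length(nb))
        D[v, , ] <- apply(D[nb, , , drop = FALSE], c(2, 3), mean)
    }
  }
  attr(D, "G") <- G
  attr(D, "flagged") <- flagged
  D
}

#' Ring-distance Gaussian smoothing operator
#'
#' Sparse row-stochastic operator averaging each vertex with its first- and
#' second-order ring neighbors, weights `w(r) = exp(-r^2 / (2 sigma^2))`
#' with `r` the ring index (0, 1, 2), truncated at ring 2.
#'
#' @param faces Mesh connectivity.
#' @param n_vertices Vertex count.
#' @param sigma Spatial bandwidth in ring units (> 0).
#' @return A sparse `dgCMatrix`.
#' @export
ring_gaussian_operator <- function(faces, n_vertices, sigma = 1) {
  if (!is.numeric(sigma) || sigma <= 0) stopf("sigma must be > 0")
  rings <- ring_neighbors(faces, n_vertices)
  w <- exp(-(0:2)^2 / (2 * sigma^2))
  n1 <- lengths(rings$ring1)
  n2 <- lengths(rings$ring2)
  i <- c(seq_len(n_vertices),
         rep.int(seq_len(n_vertices), n1),
         rep.int(seq_len(n_vertices), n2))
  j <- c(seq_len(n_vertices),
         unlist(rings$ring1, use.names = FALSE),
         unlist(rings$ring2, use.names = FALSE))
  x <- c(rep(w[1], n_vertices), rep(w[2], sum(n1)), rep(w[3], sum(n2)))
  op <- Matrix::sparseMatrix(i = i, j = j, x = x,
                             dims = c(n_vertices, n_vertices))
  rs <- Matrix::rowSums(op)
  Matrix::Diagonal(x = 1 / rs) %*% op
}

# discrete Gaussian over frames, reflected at the boundaries, row-stochastic
temporal_gaussian_operator <- function(n_frames, sigma = 1) {
  if (!is.numeric(sigma) || sigma <= 0) stopf("sigma must be > 0")
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  W <- matrix(0, n_frames, n_frames)
  for (t in seq_len(n_frames)) {
    idx <- t + (-r:r)
    # reflect: 0 -> 2, -1 -> 3, n+1 -> n-1 ...
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n_frames, 2L * n_frames - idx, idx)
    idx <- pmin(pmax(idx, 1L), n_frames)
    for (q in seq_along(idx)) W[t, idx[q]] <- W[t, idx[q]] + k[q]
  }
  W
}

#' Gaussian smoothing of per-vertex fields in space and time
#'
#' Spatial pass: ring-distance Gaussian over the first- and second-order
#' neighborhood (see [ring_gaussian_operator()]). Temporal pass: discrete
#' Gaussian over frames with reflected boundaries. Both passes are linear
#' and applied componentwise, so tensor symmetry is preserved.
#'
#' @param field Numeric vector (one frame, length `n_vertices`), matrix
#'   `[frame, vertex]`, or array `[frame, vertex, ...]` (e.g. tensors
#'   `[frame, vertex, 3, 3]`).
#' @param faces Mesh connectivity (fixed across frames).
#' @param spatial_sigma Ring-unit bandwidth (> 0), or `NULL` to skip.
#' @param temporal_sigma Frame-unit bandwidth (> 0), or `NULL` to skip.
#' @return Same shape as `field`.
#' @export
smooth_field <- function(field, faces, spatial_sigma = 1,
                         temporal_sigma = 1) {
  single <- is.null(dim(field))
  if (single) field <- matrix(field, nrow = 1)
  dm <- dim(field)
  nt <- dm[1]
  nv <- dm[2]
  flat <- matrix(field, nrow = nt * nv)  # columns = trailing components
  if (!is.null(spatial_sigma)) {
    W <- ring_gaussian_operator(faces, nv, spatial_sigma)
    for (cc in seq_len(ncol(flat))) {
      x <- matrix(flat[, cc], nt, nv)
      flat[, cc] <- as.vector(x %*% Matrix::t(W))
    }
  }
  if (!is.null(temporal_sigma)) {
    if (!is.numeric(temporal_sigma) || temporal_sigma <= 0)
      stopf("sigma must be > 0")
    if (nt > 1L) {
      Wt <- temporal_gaussian_operator(nt, temporal_sigma)
      for (cc in seq_len(ncol(flat)))
        flat[, cc] <- as.vector(Wt %*% matrix(flat[, cc], nt, nv))
    }
  }
  out <- array(flat, dm)
  if (single) out <- as.vector(out)
  out
}

#' Scalar strain rate from the tensor field
#'
#' `f = sqrt(lambda_1^2 + lambda_2^2 + lambda_3^2)`, computed as the
#' Frobenius norm of `D` (the two coincide for symmetric tensors).
#'
#' @param D Array whose last two dimensions are 3 x 3 tensors.
#' @return Array with the tensor dimensions dropped.
#' @export
scalar_strain_rate <- function(D) {
  dm <- dim(D)
  nd <- length(dm)
  stopifnot(dm[nd] == 3, dm[nd - 1] == 3)
  lead <- dm[seq_len(nd - 2)]
  flat <- matrix(D, nrow = prod(lead))
  out <- sqrt(rowSums(flat^2))
  if (length(lead) > 1) array(out, lead) else out
}

#' Strain-rate field of an evolving surface
#'
#' Computes the velocity field, the per-frame strain-rate tensors, applies
#' Gaussian smoothing to the tensor field (spatial then temporal) before
#' deriving the scalar field.
#'
#' @param es An `evolving_surface` (typically the fitted marker surface).
#' @param spatial_sigma,temporal_sigma Smoothing bandwidths (ring units /
#'   frames); `NULL` skips the pass.
#' @return Object of class `strain_field`: `times`, `D` `[frame, vertex,
#'   3, 3]` (smoothed), `scalar` `[frame, vertex]`, `velocity`.
#' @export
strain_field <- function(es, spatial_sigma = 1, temporal_sigma = 1) {
  vel <- velocity_field(es)
  nt <- length(es$times)
  nv <- dim(es$positions)[2]
  D <- array(NA_real_, c(nt, nv, 3, 3))
  for (k in seq_len(nt)) {
    Dk <- strain_rate_tensor(frame_positions(es, k), es$faces,
                             matrix(vel[k, , ], ncol = 3))
    D[k, , , ] <- Dk
  }
  D <- smooth_field(D, es$faces, spatial_sigma, temporal_sigma)
  structure(list(times = es$times, D = D,
                 scalar = scalar_strain_rate(D), velocity = vel,
                 spatial_sigma = spatial_sigma,
                 temporal_sigma = temporal_sigma,
                 faces = es$faces),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d frames x %d vertices; scalar range [%.3g, %.3g] /h\n",
              dim(x$D)[1], dim(x$D)[2], min(x$scalar), max(x$scalar)))
  invisible(x)
}

#' Eigen-decomposition of a strain-rate tensor field
#'
#' Eigenvalues sorted descending by signed value; each eigenvector's sign
#' is fixed by making its largest-magnitude component positive, for
#' reproducible output.
#'
#' @param D A `strain_field` or an array `[..., 3, 3]` of symmetric
#'   tensors (a single `[3, 3]` matrix is also accepted).
#' @return List with `values` (`[..., 3]`) and `vectors` (`[..., 3, 3]`,
#'   column `i` of each 3 x 3 block is the i-th eigenvector).
#' @export
strain_eigen <- function(D) {
  if (inherits(D, "strain_field")) D <- D$D
  dm <- dim(D)
  nd <- length(dm)
  stopifnot(dm[nd] == 3, dm[nd - 1] == 3)
  lead <- if (nd > 2) dm[seq_len(nd - 2)] else integer(0)
  n <- prod(c(lead, 1))
  flat <- matrix(D, nrow = n)
  vals <- matrix(NA_real_, n, 3)
  vecs <- matrix(NA_real_, n, 9)
  for (i in seq_len(n)) {
    M <- matrix(flat[i, ], 3, 3)
    M <- (M + t(M)) / 2
    e <- eigen(M, symmetric = TRUE)  # descending by value
    v <- e$vectors
    for (j in 1:3) {
      big <- which.max(abs(v[, j]))
      if (v[big, j] < 0) v[, j] <- -v[, j]
    }
    vals[i, ] <- e$values
    vecs[i, ] <- as.vector(v)
  }
  list(values = array(vals, c(lead, 3)),
       vectors = array(vecs, c(lead, 3, 3)))
}
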
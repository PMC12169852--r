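# Sphere-to-embryo registration: deform the reference sphere mesh onto each
# frame's embryo surface by descending the unsigned distance to the target,
# then chain fits across frames so vertices become Lagrangian markers.

#' Parameters controlling the surface fit
#'
#' Absolute values (`step`, `tol`) left `NULL` are resolved per target as
#' fractions of the target's median edge length (`step_frac`, `tol_frac`).
#'
#' @param step Descent step, length units, or `NULL` to use `step_frac`.
#' @param step_frac Step as a fraction of the target median edge length.
#' @param smooth_weight Weight of the tangential Laplacian smoothing term
#'   applied after each descent step (keeps vertices evenly distributed
#'   without pulling them off the surface).
#' @param tol Convergence tolerance on the maximum vertex-to-target
#'   distance, length units, or `NULL` to use `tol_frac`.
#' @param tol_frac Tolerance as a fraction of the target median edge length.
#' @param max_iter Iteration cap.
#' @param polish Extra descent iterations performed after the tolerance is
#'   first met. Because the step is clamped to the remaining distance, each
#'   polish round lands vertices essentially on the target, removing the
#'   systematic residual (up to `tol`) that the bare stopping rule leaves.
#' @param alpha Warm-start blend used by [propagate_markers()]: frame k > 0
#'   starts from `(1 - alpha) * fit[k-1] + alpha * (recentred, rescaled
#'   sphere)`. `alpha = 0` is a pure warm start.
#' @return An object of class `fit_params`.
#' @export
fit_params <- function(step = NULL, step_frac = 0.3, smooth_weight = 0.1,
                       tol = NULL, tol_frac = 0.5, max_iter = 500L,
                       polish = 2L, alpha = 0) {
  stopifnot(step_frac > 0, tol_frac > 0, max_iter >= 1, polish >= 0,
            smooth_weight >= 0, alpha >= 0, alpha <= 1)
  structure(list(step = step, step_frac = step_frac,
                 smooth_weight = smooth_weight, tol = tol,
                 tol_frac = tol_frac, max_iter = as.integer(max_iter),
                 polish = as.integer(polish), alpha = alpha),
            class = "fit_params")
}

resolve_fit_params <- function(params, target_vertices, target_faces) {
  med <- median_edge_length(target_vertices, target_faces)
  list(step = params$step %||% (params$step_frac * med),
       tol = params$tol %||% (params$tol_frac * med),
       smooth_weight = params$smooth_weight,
       max_iter = params$max_iter)
}

# row-normalized 1-ring adjacency operator (sparse), for Laplacian smoothing
adjacency_operator <- function(faces, n_vertices) {
  e <- mesh_edges(faces)
  i <- c(e[, 1], e[, 2])
  j <- c(e[, 2], e[, 1])
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n_vertices, n_vertices))
  deg <- Matrix::rowSums(a)
  deg[deg == 0] <- 1
  Matrix::Diagonal(x = 1 / deg) %*% a
}

#' Fit a source mesh onto a target surface
#'
#' Moves every source vertex along the negative gradient of its unsigned
#' distance to the target surface (direction to the exact closest point on
#' the target triangles), with the step clamped to the remaining distance,
#' followed by a small tangential Laplacian relaxation that preserves mesh
#' quality. Iterates until the maximum vertex-to-target distance falls
#' below `tol` or `max_iter` is reached. The source connectivity is never
#' modified, so the fit is a homeomorphic deformation of the source.
#'
#' @param target List with `vertices` and `faces`: the closed surface to fit.
#' @param source_vertices Initial source vertex positions (n x 3), e.g. an
#'   enclosing sphere at the first frame.
#' @param source_faces Source connectivity (shared across frames).
#' @param params A [fit_params()] object.
#' @param warn_not_enclosing Warn when the source does not enclose the
#'   target (the fit is still attempted; distance descent also works from
#'   the interior).
#' @return List with `vertices` (fitted positions), `residuals`
#'   (`max`, `mean`, `rms` distances to the target), `iterations`,
#'   `converged`, and `history` (per-iteration max/mean residuals before
#'   each move).
#' @export
fit_surface <- function(target, source_vertices, source_faces,
                        params = fit_params(), warn_not_enclosing = TRUE) {
  validate_closed_mesh(target$vertices, target$faces, "fit target")
  storage.mode(target$faces) <- "integer"
  pr <- resolve_fit_params(params, target$vertices, target$faces)
  v <- source_vertices
  ctr <- colMeans(target$vertices)
  if (warn_not_enclosing) {
    src_r <- min(sqrt(rowSums(sweep(v, 2, ctr)^2)))
    tgt_r <- max(sqrt(rowSums(sweep(target$vertices, 2, ctr)^2)))
    if (src_r < tgt_r)
      warnf("source does not enclose target (min source radius %.3g < max target radius %.3g); fitting anyway",
            src_r, tgt_r)
  }
  adj <- adjacency_operator(source_faces, nrow(v))
  hist_max <- numeric(0)
  hist_mean <- numeric(0)
  iter <- 0L
  converged <- FALSE
  polish_left <- params$polish
  repeat {
    cp <- cpp_closest_points(v, target$vertices, target$faces)
    d <- cp$dist
    hist_max <- c(hist_max, max(d))
    hist_mean <- c(hist_mean, mean(d))
    if (iter == 0L && max(d) < 0.05 * pr$tol) {
      # already on the target (e.g. a warm start on a static frame):
      # skip the descent entirely so markers stay put
      converged <- TRUE
      break
    }
    if (iter >= 1L && max(d) < pr$tol) {
      converged <- TRUE
      if (polish_left <= 0L) break
      polish_left <- polish_left - 1L
    }
    if (iter >= pr$max_iter) break
    # distance descent, step clamped to the remaining distance
    move <- pmin(pr$step, d)
    nz <- d > 0
    dir <- matrix(0, nrow(v), 3)
    dir[nz, ] <- (cp$points[nz, , drop = FALSE] - v[nz, , drop = FALSE]) /
      d[nz]
    v <- v + dir * move
    if (pr$smooth_weight > 0) {
      lap <- as.matrix(adj %*% v) - v
      n <- vertex_normals(v, source_faces)
      lap_t <- lap - n * rowSums(lap * n)
      v <- v + pr$smooth_weight * lap_t
    }
    iter <- iter + 1L
  }
  cp <- cpp_closest_points(v, target$vertices, target$faces)
  d <- cp$dist
  list(vertices = v,
       residuals = list(max = max(d), mean = mean(d),
                        rms = sqrt(mean(d^2))),
       iterations = iter,
       converged = converged,
       tol = pr$tol,
       history = data.frame(iteration = seq_along(hist_max) - 1L,
                            max = hist_max, mean = hist_mean))
}

#' Construct an evolving surface (Lagrangian marker trajectories)
#'
#' @param times Strictly increasing numeric vector, hours.
#' @param positions Array `[frame, vertex, 3]` of vertex positions.
#' @param faces Shared connectivity.
#' @param provenance `"raw_input"` or `"fitted"`.
#' @param check_self_intersections Scan each frame for self-intersections
#'   (logged as a warning, not an error: deep concavities can transiently
#'   self-graze at coarse resolution). Off by default, cost grows with
#'   frame count.
#' @return Object of class `evolving_surface`.
#' @export
evolving_surface <- function(times, positions, faces,
                             provenance = c("raw_input", "fitted"),
                             check_self_intersections = FALSE) {
  provenance <- match.arg(provenance)
  stopifnot(length(dim(positions)) == 3, dim(positions)[3] == 3,
            dim(positions)[1] == length(times))
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  storage.mode(faces) <- "integer"
  es <- structure(list(times = times, positions = positions, faces = faces,
                       provenance = provenance),
                  class = "evolving_surface")
  med_edge <- median_edge_length(frame_positions(es, 1L), faces)
  if (dim(positions)[1] > 1L) {
    med_disp <- max(vapply(seq_len(dim(positions)[1] - 1L), function(k) {
      stats::median(sqrt(rowSums((positions[k + 1L, , ] -
                                  positions[k, , ])^2)))
    }, numeric(1)))
    if (med_disp > med_edge)
      warnf("frame-to-frame median displacement (%.3g) exceeds median edge length (%.3g): outside the small-deformation regime",
            med_disp, med_edge)
  }
  if (check_self_intersections) {
    for (k in seq_len(dim(positions)[1])) {
      si <- self_intersections(frame_positions(es, k), faces, max_pairs = 1L)
      if (nrow(si) > 0)
        warnf("frame %d: self-intersecting faces detected (e.g. pair %d-%d)",
              k, si[1, 1], si[1, 2])
    }
  }
  es
}

#' Extract one frame's vertex positions
#' @param es An `evolving_surface`.
#' @param k Frame index.
#' @export
frame_positions <- function(es, k) {
  matrix(es$positions[k, , ], ncol = 3)
}

#' @export
print.evolving_surface <- function(x, ...) {
  cat(sprintf("<evolving_surface> %s: %d frames x %d vertices, t in [%.3g, %.3g] h\n",
              x$provenance, dim(x$positions)[1], dim(x$positions)[2],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Propagate Lagrangian markers across a frame sequence
#'
#' Fits the reference sphere to the first frame starting from an enclosing
#' sphere, then fits each subsequent frame starting from a linear
#' combination of the previous fit and a recentred, rescaled sphere
#' (coefficient `alpha` in [fit_params()]; `alpha = 0` is a pure warm
#' start). Because connectivity is fixed and inter-frame deformations are
#' small, fitted vertices behave as Lagrangian markers of the surface flow.
#'
#' @param frames List of closed meshes (each a list with `vertices`,
#'   `faces`), in time order.
#' @param times Strictly increasing times, hours.
#' @param base A [build_icosphere()] mesh providing connectivity and the
#'   unit-sphere shape.
#' @param params A [fit_params()] object.
#' @param enclose_factor First-frame initialization radius as a multiple of
#'   the target's maximum radius about its centroid.
#' @return An `evolving_surface` with `provenance = "fitted"` plus
#'   per-frame fit diagnostics in attribute `"fits"`. If a frame fails to
#'   converge, propagation stops there and the partial result is returned
#'   with attribute `"error_frame"`.
#' @export
propagate_markers <- function(frames, times, base, params = fit_params(),
                              enclose_factor = 1.1) {
  if (length(frames) < 2L) stopf("need at least 2 frames")
  if (length(frames) != length(times)) stopf("frames/times length mismatch")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  nv <- nrow(base$vertices)
  n_frames <- length(frames)
  positions <- array(NA_real_, c(n_frames, nv, 3))
  fits <- vector("list", n_frames)
  error_frame <- NULL

  enclosing_init <- function(target) {
    ctr <- colMeans(target$vertices)
    r <- max(sqrt(rowSums(sweep(target$vertices, 2, ctr)^2)))
    sweep(base$vertices * (enclose_factor * r), 2, ctr, "+")
  }

  init <- enclosing_init(frames[[1]])
  for (k in seq_len(n_frames)) {
    fit <- fit_surface(frames[[k]], init, base$faces, params,
                       warn_not_enclosing = FALSE)
    fits[[k]] <- fit[c("residuals", "iterations", "converged")]
    positions[k, , ] <- fit$vertices
    if (!fit$converged) {
      warnf("frame %d did not converge (max residual %.3g > tol %.3g); stopping propagation",
            k, fit$residuals$max, fit$tol)
      error_frame <- k
      positions <- positions[seq_len(k), , , drop = FALSE]
      times <- times[seq_len(k)]
      break
    }
    if (k < n_frames) {
      a <- params$alpha
      init <- if (a > 0) {
        (1 - a) * fit$vertices + a * enclosing_init(frames[[k + 1]])
      } else fit$vertices
    }
  }
  es <- evolving_surface(times, positions, base$faces, provenance = "fitted")
  attr(es, "fits") <- fits[seq_len(dim(positions)[1])]
  attr(es, "error_frame") <- error_frame
  es
}
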
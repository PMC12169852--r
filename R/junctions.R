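# Junction-based validation of the Lagrangian markers: detect 3-cell
# junctions from per-cell surface meshes, track them across frames by
# member-cell identity, and measure the relative displacement between each
# junction and its nearest marker.

cell_barycenters <- function(cell) {
  face_normals_areas(cell$vertices, cell$faces)$centroids
}

pooled_median_edge <- function(cells) {
  stats::median(unlist(lapply(cells, function(cl) {
    e <- mesh_edges(cl$faces)
    sqrt(rowSums((cl$vertices[e[, 1], , drop = FALSE] -
                  cl$vertices[e[, 2], , drop = FALSE])^2))
  }), use.names = FALSE))
}

# greedy single-pass spatial clustering: a point joins the first cluster
# whose running mean is within `radius`, else starts a new one
greedy_clusters <- function(pts, radius) {
  n <- nrow(pts)
  lab <- integer(n)
  means <- list()
  counts <- integer(0)
  for (p in seq_len(n)) {
    hit <- 0L
    for (q in seq_along(means)) {
      if (sqrt(sum((pts[p, ] - means[[q]])^2)) < radius) {
        hit <- q
        break
      }
    }
    if (hit) {
      means[[hit]] <- (means[[hit]] * counts[hit] + pts[p, ]) /
        (counts[hit] + 1)
      counts[hit] <- counts[hit] + 1L
      lab[p] <- hit
    } else {
      means[[length(means) + 1L]] <- pts[p, ]
      counts <- c(counts, 1L)
      lab[p] <- length(means)
    }
  }
  lab
}

# boolean near-relations between two barycenter sets within tol
near_pairs <- function(a, b, tol) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2 < tol^2
}

#' Detect 3-cell junctions in one frame
#'
#' For every maximal set of three or more cells whose surface triangles
#' come mutually close (pairwise triangle-barycenter distance below
#' `contact_tol`), emits one junction at the mean of the participating
#' barycenters. Junction identity is keyed on the member-cell set (with an
#' ordinal suffix when the same set meets at several distinct places).
#'
#' @param cells Named list of closed per-cell meshes (`vertices`, `faces`).
#' @param contact_tol Contact distance, length units; default 1.5 x the
#'   pooled median cell-mesh edge length.
#' @return Data frame (`id`, `x`, `y`, `z`, `n_members`) with the member
#'   id sets in attribute `"members"`. Zero rows when no 3-cell contact
#'   exists.
#' @export
detect_junctions <- function(cells, contact_tol = NULL) {
  n <- length(cells)
  empty <- function() {
    out <- data.frame(id = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), n_members = integer(0))
    attr(out, "members") <- list()
    out
  }
  if (n < 3L) return(empty())  # junctions need >= 3 cells in contact
  if (is.null(names(cells)) || anyDuplicated(names(cells)))
    stopf("cells must be uniquely named")
  tol <- contact_tol %||% (1.5 * pooled_median_edge(cells))
  bary <- lapply(cells, cell_barycenters)
  lo <- lapply(bary, function(b) apply(b, 2, min) - tol)
  hi <- lapply(bary, function(b) apply(b, 2, max) + tol)
  near <- vector("list", n * n)  # near[[(i-1)*n+j]]: rows of i near j
  contact <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (any(lo[[i]] > hi[[j]] + tol) || any(lo[[j]] > hi[[i]] + tol)) next
      np <- near_pairs(bary[[i]], bary[[j]], tol)
      if (!any(np)) next
      contact[i, j] <- contact[j, i] <- TRUE
      near[[(i - 1) * n + j]] <- rowSums(np) > 0
      near[[(j - 1) * n + i]] <- colSums(np) > 0
    }
  }
  juncs <- list()
  for (i in seq_len(max(0, n - 2))) {
    for (j in if (i + 1 <= n - 1) (i + 1):(n - 1) else integer(0)) {
      if (!contact[i, j]) next
      for (k in (j + 1):n) {
        if (!contact[i, k] || !contact[j, k]) next
        sel_i <- near[[(i - 1) * n + j]] & near[[(i - 1) * n + k]]
        sel_j <- near[[(j - 1) * n + i]] & near[[(j - 1) * n + k]]
        sel_k <- near[[(k - 1) * n + i]] & near[[(k - 1) * n + j]]
        if (!any(sel_i) || !any(sel_j) || !any(sel_k)) next
        pts <- rbind(bary[[i]][sel_i, , drop = FALSE],
                     bary[[j]][sel_j, , drop = FALSE],
                     bary[[k]][sel_k, , drop = FALSE])
        src <- rep(c(i, j, k), c(sum(sel_i), sum(sel_j), sum(sel_k)))
        # the same three cells can meet at several distinct sites
        # (e.g. antipodal triple points): cluster spatially first
        cl <- greedy_clusters(pts, 3 * tol)
        for (g in unique(cl)) {
          at <- cl == g
          if (length(unique(src[at])) < 3L) next
          juncs[[length(juncs) + 1L]] <-
            list(pos = colMeans(pts[at, , drop = FALSE]),
                 members = c(i, j, k), weight = sum(at))
        }
      }
    }
  }
  if (!length(juncs)) return(empty())
  # merge triples meeting at the same place (>= 4-cell corners, or the same
  # physical junction found via several triples)
  merged <- list()
  for (jn in juncs) {
    hit <- 0L
    for (q in seq_along(merged)) {
      if (sqrt(sum((merged[[q]]$pos - jn$pos)^2)) < tol &&
          length(intersect(merged[[q]]$members, jn$members)) >= 2) {
        hit <- q
        break
      }
    }
    if (hit) {
      w1 <- merged[[hit]]$weight
      w2 <- jn$weight
      merged[[hit]]$pos <- (merged[[hit]]$pos * w1 + jn$pos * w2) / (w1 + w2)
      merged[[hit]]$members <- union(merged[[hit]]$members, jn$members)
      merged[[hit]]$weight <- w1 + w2
    } else {
      merged[[length(merged) + 1L]] <- jn
    }
  }
  nm <- names(cells)
  keys <- vapply(merged, function(jn)
    paste(sort(nm[jn$members]), collapse = "+"), character(1))
  ids <- keys
  for (key in unique(keys[duplicated(keys)])) {
    at <- which(keys == key)
    ids[at] <- paste0(key, "#", seq_along(at))
  }
  pos <- do.call(rbind, lapply(merged, `[[`, "pos"))
  out <- data.frame(id = ids, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    n_members = vapply(merged, function(jn)
                      length(jn$members), integer(1)))
  attr(out, "members") <- stats::setNames(
    lapply(merged, function(jn) sort(nm[jn$members])), ids)
  out
}

#' Assemble junction tracks from per-frame detections
#'
#' Matches junctions across frames by their member-cell set. When the same
#' set meets at several places (duplicate keys), matching falls back to
#' proximity to the junction's last known position.
#'
#' @param detections List (one per frame) of [detect_junctions()] outputs.
#' @param times Frame times.
#' @return List of tracks: each has `id`, `members`, `positions` (matrix
#'   `[frame, 3]`, `NA` where undefined).
#' @export
junction_tracks <- function(detections, times) {
  stopifnot(length(detections) == length(times))
  nt <- length(times)
  tracks <- list()
  base_key <- function(id) sub("#[0-9]+$", "", id)
  for (k in seq_len(nt)) {
    det <- detections[[k]]
    if (!nrow(det)) next
    used <- character(0)
    for (r in seq_len(nrow(det))) {
      key <- base_key(det$id[r])
      pos <- as.numeric(det[r, c("x", "y", "z")])
      cand <- setdiff(names(tracks)[vapply(names(tracks), function(tid)
        base_key(tid) == key, logical(1))], used)
      if (length(cand)) {
        dists <- vapply(cand, function(tid) {
          p <- tracks[[tid]]$positions
          last <- max(which(!is.na(p[, 1])), -Inf)
          if (!is.finite(last)) return(Inf)
          sqrt(sum((p[last, ] - pos)^2))
        }, numeric(1))
        tid <- cand[which.min(dists)]
      } else {
        tid <- det$id[r]
        while (tid %in% names(tracks)) tid <- paste0(tid, "'")
        tracks[[tid]] <- list(id = tid, members =
                                attr(det, "members")[[det$id[r]]],
                              positions = matrix(NA_real_, nt, 3))
      }
      tracks[[tid]]$positions[k, ] <- pos
      used <- c(used, tid)
    }
  }
  tracks
}

#' Mean apical edge length of a cell collection
#'
#' Uses the outward-facing (apical) triangles when cells carry an `apical`
#' face-index vector, otherwise all cell-surface edges.
#'
#' @param cells Named list of cell meshes.
#' @export
apex_edge_length <- function(cells) {
  lens <- unlist(lapply(cells, function(cl) {
    f <- cl$faces
    if (!is.null(cl$apical)) f <- f[cl$apical, , drop = FALSE]
    e <- mesh_edges(f)
    sqrt(rowSums((cl$vertices[e[, 1], , drop = FALSE] -
                  cl$vertices[e[, 2], , drop = FALSE])^2))
  }), use.names = FALSE)
  mean(lens)
}

#' Relative junction-marker displacement error
#'
#' Each junction is paired with its nearest fitted vertex (marker) at the
#' first frame where the junction exists; the marker is then followed by
#' index. The per-step contribution is the absolute change of the
#' junction-marker distance between consecutive frames, normalized by the
#' apical edge length; the series reports the per-frame mean over
#' junctions. Small values mean markers co-move with the tissue.
#'
#' @param tracks Output of [junction_tracks()].
#' @param fitted An `evolving_surface` of fitted markers sharing the time
#'   axis.
#' @param apex_edge Normalization length; see [apex_edge_length()].
#' @return List with `series` (data frame `frame`, `time`, `mean_error`,
#'   `n_junctions`) and `per_junction` (named mean error per junction).
#' @export
junction_displacement_error <- function(tracks, fitted, apex_edge) {
  nt <- length(fitted$times)
  per_step <- matrix(NA_real_, length(tracks), nt - 1L)
  per_junction <- stats::setNames(rep(NA_real_, length(tracks)),
                                  names(tracks))
  for (q in seq_along(tracks)) {
    tr <- tracks[[q]]
    defined <- which(!is.na(tr$positions[, 1]))
    if (length(defined) < 2L) {
      ms_log("junction %s defined at < 2 frames: skipped", tr$id)
      next
    }
    k0 <- defined[1]
    fp <- frame_positions(fitted, k0)
    marker <- which.min(rowSums(sweep(fp, 2, tr$positions[k0, ])^2))
    d <- rep(NA_real_, nt)
    for (k in defined)
      d[k] <- sqrt(sum((tr$positions[k, ] -
                        fitted$positions[k, marker, ])^2))
    for (k in seq_len(nt - 1L)) {
      if (!is.na(d[k]) && !is.na(d[k + 1]))
        per_step[q, k] <- abs(d[k + 1] - d[k]) / apex_edge
    }
    per_junction[q] <- mean(per_step[q, ], na.rm = TRUE)
  }
  n_def <- colSums(!is.na(per_step))
  mean_err <- ifelse(n_def > 0, colMeans(per_step, na.rm = TRUE), NA_real_)
  list(series = data.frame(frame = 2:nt, time = fitted$times[-1],
                           mean_error = mean_err, n_junctions = n_def),
       per_junction = per_junction)
}
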
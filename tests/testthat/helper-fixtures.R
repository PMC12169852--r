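# Shared fixtures, built in code and cached for the test run.

.ico_cache <- new.env(parent = emptyenv())

ico <- function(level) {
  key <- as.character(level)
  if (is.null(.ico_cache[[key]]))
    .ico_cache[[key]] <- build_icosphere(level)
  .ico_cache[[key]]
}

# evolving_surface -> list of per-frame meshes (pipeline input form)
frames_of <- function(es) {
  lapply(seq_along(es$times), function(k)
    list(vertices = frame_positions(es, k), faces = es$faces))
}

# axis-aligned closed box mesh (12 triangles), outward orientation
box_mesh <- function(lo, hi) {
  g <- expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                   z = c(lo[3], hi[3]))
  v <- as.matrix(g)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = lo
    c(5, 6, 7), c(6, 8, 7),  # z = hi
    c(1, 2, 5), c(2, 6, 5),  # y = lo
    c(3, 7, 4), c(4, 7, 8),  # y = hi
    c(1, 5, 3), c(3, 5, 7),  # x = lo
    c(2, 4, 6), c(4, 8, 6))  # x = hi
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

# brute-force unique-edge count straight from the face list
brute_edge_count <- function(faces) {
  keys <- character(0)
  for (r in seq_len(nrow(faces))) {
    tri <- faces[r, ]
    for (pr in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- min(tri[pr])
      b <- max(tri[pr])
      keys <- c(keys, paste(a, b))
    }
  }
  length(unique(keys))
}

# rigid-rotation velocity field omega x v
rotation_velocity <- function(vertices, omega) {
  cbind(omega[2] * vertices[, 3] - omega[3] * vertices[, 2],
        omega[3] * vertices[, 1] - omega[1] * vertices[, 3],
        omega[1] * vertices[, 2] - omega[2] * vertices[, 1])
}
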
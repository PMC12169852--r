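# Mesh file I/O: ASCII and binary-little-endian PLY, Wavefront OBJ, and
# legacy ASCII VTK polydata. Only triangle connectivity and vertex
# positions are handled; that is all the pipeline consumes.

#' Write a triangle mesh as PLY
#'
#' @param mesh List with `vertices` and `faces` (a `sphere_mesh` works).
#' @param path Output file.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @param comment Optional header comment line(s).
#' @export
write_ply <- function(mesh, path, format = c("ascii",
                                             "binary_little_endian"),
                      comment = NULL) {
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  hdr <- c("ply",
           sprintf("format %s 1.0", format),
           paste("comment", comment %||% "morphospectra surface mesh"),
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(v)), con, size = 8, endian = "little")
    # uchar count followed by three int32 indices, per face
    for (k in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[k, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY triangle mesh (ASCII or binary little-endian)
#'
#' Supports `float`/`double` vertex properties named x, y, z (extra vertex
#' properties are skipped in ASCII, rejected in binary) and uchar-counted
#' integer face lists.
#'
#' @param path PLY file.
#' @return List with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stopf("%s: truncated PLY header", path)
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  if (hdr[1] != "ply") stopf("%s: not a PLY file", path)
  fmt <- strsplit(grep("^format", hdr, value = TRUE)[1], "\\s+")[[1]][2]
  elems <- grep("^element", hdr)
  get_count <- function(name) {
    at <- grep(sprintf("^element %s", name), hdr)
    if (!length(at)) stopf("%s: no %s element", path, name)
    as.integer(strsplit(hdr[at], "\\s+")[[1]][3])
  }
  nv <- get_count("vertex")
  nf <- get_count("face")
  vat <- grep("^element vertex", hdr)
  vprops <- character(0)
  for (k in seq(vat + 1, length(hdr))) {
    if (!grepl("^property", hdr[k])) break
    vprops <- c(vprops, hdr[k])
  }
  ptypes <- vapply(strsplit(vprops, "\\s+"), `[`, character(1), 2)
  pnames <- vapply(strsplit(vprops, "\\s+"), `[`, character(1), 3)
  if (fmt == "ascii") {
    txt <- readLines(con)
    vl <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    vm <- do.call(rbind, lapply(vl, function(x) as.numeric(x)))
    xyz <- match(c("x", "y", "z"), pnames)
    if (anyNA(xyz)) stopf("%s: vertex element lacks x/y/z", path)
    v <- vm[, xyz, drop = FALSE]
    fl <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    f <- do.call(rbind, lapply(fl, function(x) {
      n <- as.integer(x[1])
      if (n != 3L) stopf("%s: non-triangular face", path)
      as.integer(x[2:4]) + 1L
    }))
  } else if (fmt == "binary_little_endian") {
    if (!identical(pnames, c("x", "y", "z")))
      stopf("%s: binary reader expects exactly x, y, z vertex properties",
            path)
    sz <- ifelse(ptypes %in% c("double", "float64"), 8L, 4L)
    if (length(unique(sz)) != 1L)
      stopf("%s: mixed vertex property sizes unsupported", path)
    raw_v <- readBin(con, "double", n = 3 * nv, size = sz[1],
                     endian = "little")
    v <- matrix(raw_v, nv, 3, byrow = TRUE)
    f <- matrix(NA_integer_, nf, 3)
    for (k in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      if (cnt != 3L) stopf("%s: non-triangular face", path)
      f[k, ] <- readBin(con, "integer", n = 3, size = 4,
                        endian = "little") + 1L
    }
  } else stopf("%s: unsupported PLY format '%s'", path, fmt)
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

#' Write a triangle mesh as Wavefront OBJ
#' @inheritParams write_ply
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines("# morphospectra surface mesh", con)
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ triangle mesh
#' @param path OBJ file.
#' @return List with `vertices` and `faces`.
#' @export
read_obj <- function(path) {
  txt <- readLines(path)
  vl <- grep("^v ", txt, value = TRUE)
  fl <- grep("^f ", txt, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    idx <- sub("/.*$", "", x[-1])  # drop texture/normal refs
    if (length(idx) != 3L) stopf("%s: non-triangular face", path)
    as.integer(idx)
  }))
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

#' Write a triangle mesh as legacy ASCII VTK polydata
#' @inheritParams write_ply
#' @export
write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c("# vtk DataFile Version 3.0",
               "morphospectra surface mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}

#' Read a legacy ASCII VTK polydata triangle mesh
#' @param path VTK file.
#' @return List with `vertices` and `faces`.
#' @export
read_vtk <- function(path) {
  txt <- readLines(path)
  pat <- grep("^POINTS", txt)
  if (!length(pat)) stopf("%s: no POINTS section", path)
  nv <- as.integer(strsplit(txt[pat[1]], "\\s+")[[1]][2])
  fat <- grep("^POLYGONS", txt)
  if (!length(fat)) stopf("%s: no POLYGONS section", path)
  nums <- as.numeric(unlist(strsplit(trimws(
    paste(txt[(pat[1] + 1):(fat[1] - 1)], collapse = " ")), "\\s+")))
  v <- matrix(nums[seq_len(3 * nv)], nv, 3, byrow = TRUE)
  nf <- as.integer(strsplit(txt[fat[1]], "\\s+")[[1]][2])
  fl <- strsplit(trimws(txt[fat[1] + seq_len(nf)]), "\\s+")
  f <- do.call(rbind, lapply(fl, function(x) {
    if (as.integer(x[1]) != 3L) stopf("%s: non-triangular polygon", path)
    as.integer(x[2:4]) + 1L
  }))
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

#' Read a mesh, dispatching on the file extension
#' @param path `.ply`, `.obj` or `.vtk` file.
#' @return List with `vertices` and `faces`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         vtk = read_vtk(path),
         stopf("unsupported mesh format '.%s' (PLY/OBJ/VTK)", ext))
}

#' Read a time-ordered frame sequence from a manifest
#'
#' The manifest is a CSV with columns `file` (mesh path, relative to the
#' manifest location) and `time` (hours; a `unit` column with value
#' `"minutes"` rescales). Frames may mix formats. Each mesh is validated
#' as a closed 2-manifold; open meshes error with the frame named and the
#' boundary-edge count.
#'
#' @param manifest Path to the manifest CSV.
#' @param axis_permutation Optional length-3 signed permutation such as
#'   `c(2, 3, 1)` or `c(1, -3, 2)` mapping input axes onto (x, y, z) so
#'   the animal-vegetal axis ends up on +z; applied at read time.
#' @return List with `frames` (list of meshes) and `times`.
#' @export
read_frames <- function(manifest, axis_permutation = NULL) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("file", "time") %in% names(tab)))
    stopf("manifest must have 'file' and 'time' columns")
  times <- as.numeric(tab$time)
  if ("unit" %in% names(tab) && any(tab$unit == "minutes"))
    times[tab$unit == "minutes"] <- times[tab$unit == "minutes"] / 60
  if (anyNA(times)) stopf("missing timestamp in manifest")
  if (any(diff(times) <= 0)) stopf("manifest times must strictly increase")
  root <- dirname(manifest)
  frames <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    p <- tab$file[k]
    if (!file.exists(p)) p <- file.path(root, tab$file[k])
    mesh <- read_mesh(p)
    chk <- is_closed_mesh(mesh$faces)
    if (!chk$closed)
      stopf("frame %d (%s) is not closed: %d boundary edge(s)", k,
            tab$file[k], chk$n_boundary_edges)
    if (!is.null(axis_permutation))
      mesh$vertices <- apply_axis_permutation(mesh$vertices,
                                              axis_permutation)
    frames[[k]] <- mesh
  }
  list(frames = frames, times = times)
}

apply_axis_permutation <- function(vertices, perm) {
  stopifnot(length(perm) == 3, all(abs(perm) %in% 1:3),
            !anyDuplicated(abs(perm)))
  out <- vertices[, abs(perm), drop = FALSE] *
    matrix(sign(perm), nrow(vertices), 3, byrow = TRUE)
  colnames(out) <- NULL
  out
}
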
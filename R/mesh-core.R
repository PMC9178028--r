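#' Triangle-mesh data model for digital dental models
#'
#' A `tri_mesh` is an indexed triangle surface: an `n x 3` numeric matrix of
#' vertex coordinates in millimetres and an `m x 3` integer matrix of
#' 1-based vertex indices per face. Vertex normals (unit, outward-facing)
#' are computed lazily by [vertex_normals()]. The coordinate convention is
#' right-handed with the occlusal direction along +z after orientation.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit vertex normals.
#' @param validate check invariants (finite coordinates, in-range indices,
#'   no degenerate faces). Disable only for meshes built by trusted code.
#' @return an object of class `tri_mesh` with elements `vertices`, `faces`
#'   and optionally `normals`.
#' @export
tri_mesh <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as_mat3(vertices, "vertices")
  faces <- as_face_mat(faces)
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "tri_mesh")
  if (!is.null(normals)) mesh$normals <- as_mat3(normals, "normals")
  if (validate) validate_tri_mesh(mesh)
  mesh
}

as_mat3 <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(what, " must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

as_face_mat <- function(faces) {
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  faces
}

validate_tri_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) stop("empty mesh: zero faces", call. = FALSE)
  if (!all(is.finite(v))) stop("non-finite vertex coordinates", call. = FALSE)
  if (any(f < 1L) || any(f > nrow(v)))
    stop("face index out of range [1, n_vertices]", call. = FALSE)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  if (any(degen))
    stop("degenerate face(s) with repeated vertex: ",
         paste(utils::head(which(degen), 5), collapse = ", "), call. = FALSE)
  if (!is.null(mesh$normals)) {
    nrm <- sqrt(rowSums(mesh$normals^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("vertex normals must be unit length", call. = FALSE)
  }
  invisible(mesh)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", if (!is.null(x$normals)) ", with normals", "\n", sep = "")
  invisible(x)
}

#' Number of vertices / faces
#' @param mesh a [tri_mesh()].
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# per-face unit normals and areas (right-hand rule)
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(cr^2))
  list(normals = cr / pmax(len, .Machine$double.eps), areas = len / 2)
}

#' Total surface area of a mesh
#' @param mesh a [tri_mesh()].
#' @return area in mm^2.
#' @export
surface_area <- function(mesh) sum(face_normals(mesh)$areas)

#' Area-weighted outward vertex normals
#' @param mesh a [tri_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  w <- fn$normals * fn$areas
  acc <- matrix(0, n_vertices(mesh), 3)
  for (j in 1:3) {
    idx <- mesh$faces[, j]
    acc[, 1] <- acc[, 1] + unname(rowsum_vec(w[, 1], idx, n_vertices(mesh)))
    acc[, 2] <- acc[, 2] + unname(rowsum_vec(w[, 2], idx, n_vertices(mesh)))
    acc[, 3] <- acc[, 3] + unname(rowsum_vec(w[, 3], idx, n_vertices(mesh)))
  }
  len <- sqrt(rowSums(acc^2))
  acc / pmax(len, .Machine$double.eps)
}

# sum values by integer group over a fixed range 1..n
rowsum_vec <- function(values, group, n) {
  out <- numeric(n)
  s <- rowsum(values, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Per-vertex label map over a mesh
#'
#' Labels follow the seventeen-class scheme: 0 = gingiva, 1..16 = intra-arch
#' tooth positions (1..8 on the patient's right, 9..16 on the left, mesial
#' to distal). The coarse two-class view is simply `labels > 0`.
#'
#' @param labels integer vector, one label in 0..16 per vertex.
#' @param mesh the mesh the labels refer to (for the length invariant).
#' @return an integer vector of class `label_map`.
#' @export
label_map <- function(labels, mesh = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0L) || any(labels > 16L))
    stop("labels must be integers in 0..16", call. = FALSE)
  if (!is.null(mesh) && length(labels) != n_vertices(mesh))
    stop("label map length (", length(labels), ") must equal vertex count (",
         n_vertices(mesh), ")", call. = FALSE)
  structure(labels, class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = 0:16))
  cat("<label_map> ", length(x), " vertices; gingiva ", tab["0"],
      "; teeth present: ", paste(names(tab)[-1][tab[-1] > 0], collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Class names for the seventeen-class scheme
#' @return named character vector mapping labels "0".."16" to names.
#' @export
label_class_names <- function() {
  pos <- c(paste0("R", 1:8), paste0("L", 1:8))
  stats::setNames(c("gingiva", pos), as.character(0:16))
}

## ---------------------------------------------------------------- file I/O

#' Read a triangle mesh from STL, PLY or OBJ
#'
#' STL (binary and ASCII dialects) carries no vertex indexing: coincident
#' vertices are welded by exact coordinate hashing (no tolerance merge) so
#' that label propagation stays deterministic. PLY (ASCII) and OBJ preserve
#' the stored vertex order. A PLY per-vertex integer property `label`, when
#' present, is returned as attribute `"labels"`.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; default guesses from the
#'   file extension.
#' @return a [tri_mesh()]; PLY labels, if stored, attached as
#'   `attr(mesh, "labels")`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format: ", format, call. = FALSE))
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' @param mesh a valid [tri_mesh()].
#' @param path output path.
#' @param format `"stl"` (binary by default), `"ply"` (ASCII) or `"obj"`.
#' @param labels optional [label_map()] stored as PLY property `label`
#'   (PLY only; other formats need a sidecar, see [write_labels()]).
#' @param ascii for STL, write the ASCII dialect instead of binary.
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = NULL, labels = NULL, ascii = FALSE) {
  validate_tri_mesh(mesh)
  if (n_vertices(mesh) == 0L) stop("refusing to write empty-vertex mesh", call. = FALSE)
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         stl = write_stl(mesh, path, ascii = ascii),
         ply = write_ply(mesh, path, labels = labels),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: ", format, call. = FALSE))
  invisible(path)
}

# weld triangle soup into an indexed mesh by exact coordinate identity
weld_soup <- function(tri_coords) {
  # tri_coords: (3*m) x 3, consecutive triples are one triangle
  key <- paste(sprintf("%.17g", tri_coords[, 1]),
               sprintf("%.17g", tri_coords[, 2]),
               sprintf("%.17g", tri_coords[, 3]))
  first <- !duplicated(key)
  verts <- tri_coords[first, , drop = FALSE]
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

stl_is_binary <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  header <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) return(TRUE)
  !identical(rawToChar(header[1:5]), "solid")
}

read_stl <- function(path) {
  if (stl_is_binary(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  if (sz < expected)
    stop("truncated binary STL: expected ", expected, " bytes, file has ",
         sz, " (short at byte offset ", sz, ")", call. = FALSE)
  if (ntri == 0L) stop("empty mesh: STL declares zero facets", call. = FALSE)
  raw <- readBin(con, "raw", 50 * ntri)
  m <- matrix(raw, nrow = 50)
  tri <- matrix(0, 3 * ntri, 3)
  for (corner in 1:3) {
    off <- 12 * corner            # skip 12-byte facet normal, then corners
    for (axis in 1:3) {
      bytes <- m[off + (axis - 1) * 4 + 1:4, , drop = FALSE]
      tri[seq(corner, by = 3, length.out = ntri), axis] <-
        readBin(as.vector(bytes), "double", ntri, size = 4, endian = "little")
    }
  }
  # rows already grouped as consecutive corner triples per facet
  weld_soup(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L) stop("empty mesh: no vertices in ASCII STL", call. = FALSE)
  if (length(vl) %% 3 != 0)
    stop("truncated ASCII STL: vertex count ", length(vl),
         " not a multiple of 3 (near line ",
         utils::tail(grep("^\\s*vertex\\s", lines), 1), ")", call. = FALSE)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(nums)) stop("unparseable vertex line in ASCII STL", call. = FALSE)
  weld_soup(nums)
}

write_stl <- function(mesh, path, ascii = FALSE) {
  fn <- face_normals(mesh)$normals
  v <- mesh$vertices; f <- mesh$faces
  if (ascii) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid dentseg", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                           fn[i, 1], fn[i, 2], fn[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid dentseg", con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(fn[i, ], t(v[f[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end_hdr <- match("end_header", trimws(lines))
  if (is.na(end_hdr)) stop("not a PLY file (no end_header): ", path, call. = FALSE)
  hdr <- trimws(lines[seq_len(end_hdr)])
  if (!identical(hdr[1], "ply")) stop("not a PLY file: ", path, call. = FALSE)
  fmt <- grep("^format ", hdr, value = TRUE)
  if (!grepl("ascii", fmt)) stop("only ASCII PLY supported", call. = FALSE)
  el <- grep("^element ", hdr)
  nv <- nf <- 0L; vprops <- character()
  for (i in el) {
    p <- strsplit(hdr[i], "\\s+")[[1]]
    if (p[2] == "vertex") {
      nv <- as.integer(p[3])
      j <- i + 1
      while (j <= end_hdr && grepl("^property ", hdr[j])) {
        vprops <- c(vprops, utils::tail(strsplit(hdr[j], "\\s+")[[1]], 1))
        j <- j + 1
      }
    } else if (p[2] == "face") nf <- as.integer(p[3])
  }
  if (nf == 0L) stop("empty mesh: PLY declares zero faces", call. = FALSE)
  body <- lines[(end_hdr + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf)
    stop("truncated PLY: expected ", nv + nf, " body lines, found ",
         length(body), call. = FALSE)
  vdat <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(nv)]), "\\s+"))),
                 nrow = nv, byrow = TRUE)
  verts <- vdat[, match(c("x", "y", "z"), vprops), drop = FALSE]
  faces <- t(vapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                    function(p) {
                      if (as.integer(p[1]) != 3L)
                        stop("non-triangular PLY face", call. = FALSE)
                      as.integer(p[2:4]) + 1L
                    }, integer(3)))
  mesh <- tri_mesh(verts, faces)
  if ("label" %in% vprops)
    attr(mesh, "labels") <- label_map(vdat[, match("label", vprops)], mesh)
  mesh
}

write_ply <- function(mesh, path, labels = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  if (!is.null(labels) && length(labels) != nrow(v))
    stop("labels length must equal vertex count", call. = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(v)),
           "property float x", "property float y", "property float z",
           if (!is.null(labels)) "property int label",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  if (is.null(labels)) {
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g %d", v[, 1], v[, 2], v[, 3],
                       as.integer(labels)), con)
  }
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(fl) == 0L) stop("empty mesh: OBJ has no faces", call. = FALSE)
  verts <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(p) as.numeric(p[2:4]), numeric(3)))
  faces <- t(vapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- as.integer(sub("/.*", "", p[-1]))
    if (length(idx) != 3L) stop("non-triangular OBJ face", call. = FALSE)
    idx
  }, integer(3)))
  tri_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Read / write a per-vertex label sidecar file
#'
#' One integer per line, aligned with mesh vertex order. This is the
#' round-trip carrier for labels next to STL/OBJ geometry.
#'
#' @param path text file path.
#' @param labels a [label_map()] or integer vector.
#' @param mesh optional mesh to check the length invariant against.
#' @return `read_labels()` returns a [label_map()].
#' @export
read_labels <- function(path, mesh = NULL) {
  label_map(as.integer(readLines(path, warn = FALSE)), mesh)
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

## ---------------------------------------------------- adjacency / submesh

#' Vertex adjacency of a triangle mesh
#'
#' @param mesh a [tri_mesh()].
#' @return list of length `n_vertices(mesh)`; element `i` is the sorted
#'   integer vector of vertices sharing an edge with `i`. The relation is
#'   symmetric and irreflexive.
#' @export
build_adjacency <- function(mesh) {
  f <- mesh$faces
  ea <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  eb <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  adj <- split(eb, factor(ea, levels = seq_len(n_vertices(mesh))))
  lapply(adj, function(x) sort(unique(x)))
}

# undirected edge list (u < v) with lengths
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = len)
}

# boundary vertex indices: vertices on edges used by exactly one face
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0L) return(integer(0))
  sort(unique(as.integer(unlist(strsplit(bkey, " ")))))
}

#' Extract the submesh of one label
#'
#' Keeps exactly the faces whose three vertices all carry `target_label`
#' (vertex-homogeneous rule: faces straddling two labels belong to no
#' submesh, which keeps the margin line crisp). Vertices are re-indexed
#' compactly.
#'
#' @param mesh a [tri_mesh()].
#' @param labels a [label_map()] over `mesh`.
#' @param target_label integer label in 0..16.
#' @return list with `mesh` (the submesh) and `vmap` (integer vector mapping
#'   submesh vertex index to source vertex index).
#' @export
extract_labeled_submesh <- function(mesh, labels, target_label) {
  labels <- as.integer(labels)
  if (length(labels) != n_vertices(mesh))
    stop("labels length must equal vertex count", call. = FALSE)
  if (!any(labels == target_label))
    stop("label ", target_label, " absent from label map", call. = FALSE)
  f <- mesh$faces
  keep <- labels[f[, 1]] == target_label &
    labels[f[, 2]] == target_label &
    labels[f[, 3]] == target_label
  if (!any(keep))
    stop("label ", target_label,
         " has no label-homogeneous faces", call. = FALSE)
  fs <- f[keep, , drop = FALSE]
  vmap <- sort(unique(as.vector(fs)))
  new_idx <- integer(n_vertices(mesh))
  new_idx[vmap] <- seq_along(vmap)
  sub <- tri_mesh(mesh$vertices[vmap, , drop = FALSE],
                  matrix(new_idx[fs], ncol = 3))
  list(mesh = sub, vmap = vmap)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
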
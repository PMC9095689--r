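#' Triangulated surface mesh
#'
#' Construct a `surface_mesh`: an ordered set of 3-D vertices (millimetres)
#' plus triangle connectivity. This is the package's geometric container; a
#' specimen's segmented muscle surface is one `surface_mesh`.
#'
#' The package-wide anatomical frame is: x = medial--lateral,
#' y = anterior--posterior, z = proximal(superior)--distal(inferior), with the
#' right limb as the canonical side. `frame_note` records the convention
#' carried by a particular mesh.
#'
#' @param vertices numeric matrix, n x 3, one vertex per row, millimetres.
#' @param faces integer matrix, f x 3, 1-based vertex indices per triangle.
#' @param frame_note character tag describing the coordinate convention.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `frame_note`.
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                   rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
#' n_vertices(m)
#' @export
surface_mesh <- function(vertices, faces,
                         frame_note = "x:medial-lateral y:anterior-posterior z:proximal-distal, right limb") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  mesh <- structure(
    list(vertices = vertices, faces = faces, frame_note = frame_note),
    class = "surface_mesh"
  )
  validate_surface_mesh(mesh)
  mesh
}

validate_surface_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L) {
    abort_format("vertices must be an n x 3 matrix")
  }
  if (nrow(v) < 4L) {
    abort_format(sprintf("a surface mesh needs at least 4 vertices, got %d", nrow(v)))
  }
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1L, ]
    abort_format(sprintf("non-finite coordinate at vertex %d", bad[[1L]]))
  }
  if (!is.matrix(f) || ncol(f) != 3L || nrow(f) < 1L) {
    abort_format("faces must be an f x 3 matrix with at least one triangle")
  }
  if (any(f < 1L) || any(f > nrow(v))) {
    bad <- which(f < 1L | f > nrow(v), arr.ind = TRUE)[1L, 1L]
    abort_format(sprintf("face %d references a vertex outside 1..%d", bad, nrow(v)))
  }
  degen <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
  if (any(degen)) {
    abort_format(sprintf("degenerate face %d (repeated vertex index)", which(degen)[1L]))
  }
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("<surface_mesh: %d vertices, %d faces>\n", nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  extent (mm): x %.1f  y %.1f  z %.1f\n",
              diff(bb[, 1L]), diff(bb[, 2L]), diff(bb[, 3L])))
  cat(sprintf("  frame: %s\n", x$frame_note))
  invisible(x)
}

#' Number of vertices of a mesh or shape vector
#' @param x a `surface_mesh` or `shape_vector`.
#' @return integer vertex count.
#' @export
n_vertices <- function(x) {
  if (inherits(x, "surface_mesh")) return(nrow(x$vertices))
  if (inherits(x, "shape_vector")) return(attr(x, "n_vertices"))
  abort_parameter("n_vertices() expects a surface_mesh or shape_vector")
}

#' Flattened shape-vector representation
#'
#' A corresponded specimen is represented as a single length-3n vector of
#' vertex-major concatenated coordinates (x1, y1, z1, x2, ...), the row of the
#' data matrix that the shape model decomposes.
#'
#' @param mesh a `surface_mesh`.
#' @return a `shape_vector`: numeric length-3n vector with attribute
#'   `n_vertices`.
#' @export
mesh_to_shape_vector <- function(mesh) {
  validate_surface_mesh(mesh)
  new_shape_vector(as.numeric(t(mesh$vertices)), nrow(mesh$vertices))
}

new_shape_vector <- function(values, n_vertices) {
  if (length(values) != 3L * n_vertices) {
    abort_dimension(sprintf("shape vector length %d is not 3 x %d vertices",
                            length(values), n_vertices))
  }
  structure(as.numeric(values), n_vertices = as.integer(n_vertices),
            class = "shape_vector")
}

#' @export
print.shape_vector <- function(x, ...) {
  cat(sprintf("<shape_vector: %d vertices (%d values)>\n",
              attr(x, "n_vertices"), length(x)))
  invisible(x)
}

#' Rebuild a mesh from a shape vector and a face list
#'
#' Inverse of [mesh_to_shape_vector()]: reattaches reference topology to a
#' flattened coordinate vector (e.g. a model reconstruction).
#'
#' @param vec a `shape_vector` or plain numeric vector of length 3n.
#' @param topology f x 3 face index matrix (1-based), indices `<= n`.
#' @inheritParams surface_mesh
#' @return a `surface_mesh`.
#' @export
shape_vector_to_mesh <- function(vec, topology, frame_note = NULL) {
  nv <- if (inherits(vec, "shape_vector")) attr(vec, "n_vertices") else {
    if (length(vec) %% 3L != 0L) abort_dimension("coordinate vector length is not a multiple of 3")
    length(vec) %/% 3L
  }
  topology <- as.matrix(topology)
  storage.mode(topology) <- "integer"
  if (any(topology > nv) || any(topology < 1L)) {
    abort_dimension(sprintf("topology references vertex outside 1..%d", nv))
  }
  v <- matrix(as.numeric(vec), ncol = 3L, byrow = TRUE)
  if (is.null(frame_note)) {
    surface_mesh(v, topology)
  } else {
    surface_mesh(v, topology, frame_note = frame_note)
  }
}

# Shape vectors stacked into a 3n x m matrix (one specimen per column).
shape_vectors_to_matrix <- function(shape_vectors) {
  if (length(shape_vectors) < 1L) abort_parameter("empty shape-vector list")
  lens <- vapply(shape_vectors, length, integer(1L))
  if (length(unique(lens)) != 1L) {
    abort_dimension("shape vectors have mixed lengths")
  }
  matrix(unlist(shape_vectors, use.names = FALSE), nrow = lens[[1L]])
}

#' Reflect a mesh across the sagittal plane
#'
#' Mirrors a left-limb mesh across x = 0 (the sagittal plane under the
#' package's frame convention) so it can be pooled with right-limb specimens.
#' Face winding is reversed so outward normals stay outward.
#'
#' @param mesh a `surface_mesh`.
#' @return the reflected `surface_mesh`.
#' @export
reflect_sagittal <- function(mesh) {
  validate_surface_mesh(mesh)
  v <- mesh$vertices
  v[, 1L] <- -v[, 1L]
  f <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  surface_mesh(v, f, frame_note = mesh$frame_note)
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume from the triangle fan at the origin; positive for
#' consistently outward-wound closed surfaces.
#'
#' @param mesh a `surface_mesh`.
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  det3 <- a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
    a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
    a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  sum(det3) / 6
}

# Area-weighted outward vertex normals (unit length).
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  n <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], f[, k])
      n[as.integer(rownames(acc)), d] <- n[as.integer(rownames(acc)), d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# TRUE when every edge is shared by exactly two faces (closed 2-manifold).
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  all(table(key) == 2L)
}
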
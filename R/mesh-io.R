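#' Read a surface mesh from STL or PLY
#'
#' STL dialect (ASCII vs binary) is auto-detected. STL facet soups are welded
#' into an indexed mesh by exact coordinate equality — no tolerance, so meshes
#' written by this package round-trip bit-exactly.
#'
#' @param path file path.
#' @param format `"stl"` or `"ply"`; default guesses from the file extension.
#' @return a [surface_mesh()]; for PLY files carrying a per-vertex `quality`
#'   property, the scalars are attached as attribute `"scalars"`.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     stl = "stl", ply = "ply",
                     abort_parameter(sprintf("cannot guess mesh format of '%s'", path)))
  }
  if (!file.exists(path)) {
    abort_io(sprintf("mesh file does not exist: '%s'", path))
  }
  switch(format, stl = read_stl(path), ply = read_ply(path))
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"stl"` or `"ply"`.
#' @param scalars optional per-vertex values (PLY only; stored as float
#'   property `quality`), e.g. a difference map.
#' @param binary for STL, write the binary dialect instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply"),
                       scalars = NULL, binary = FALSE) {
  validate_surface_mesh(mesh)
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     stl = "stl", ply = "ply",
                     abort_parameter(sprintf("cannot guess mesh format of '%s'", path)))
  }
  if (!is.null(scalars)) {
    if (format == "stl") {
      abort_unsupported("STL carries geometry only; per-vertex scalars need PLY")
    }
    if (length(scalars) != nrow(mesh$vertices)) {
      abort_dimension(sprintf("scalars length %d != %d vertices",
                              length(scalars), nrow(mesh$vertices)))
    }
  }
  switch(format,
         stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path, scalars))
  invisible(path)
}

# --- STL ---------------------------------------------------------------------

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 512L)
  close(con)
  printable <- head >= as.raw(0x09) & head <= as.raw(0x7e)
  txt <- rawToChar(head[printable])
  # ASCII STL starts with "solid" AND contains "facet" early on; binary files
  # may also begin with the bytes "solid", so require the keyword.
  is_ascii <- grepl("^\\s*solid", txt) && grepl("facet|endsolid", txt)
  tri <- if (is_ascii) read_stl_ascii_tris(path) else read_stl_binary_tris(path)
  if (nrow(tri) == 0L) abort_format(sprintf("'%s': empty facet list", path))
  if (any(!is.finite(tri))) {
    bad <- ceiling(which(!is.finite(t(tri)))[1L] / 3L)
    abort_format(sprintf("'%s': non-finite coordinate in facet record %d",
                         path, ceiling(bad / 3)))
  }
  weld_triangle_soup(tri)
}

read_stl_ascii_tris <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L) abort_format(sprintf("'%s': empty facet list", path))
  if (length(vl) %% 3L != 0L) {
    abort_format(sprintf("'%s': vertex count %d is not a multiple of 3", path, length(vl)))
  }
  parts <- strsplit(trimws(vl), "\\s+")
  coords <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])), numeric(3L))
  matrix(as.numeric(coords), ncol = 3L, byrow = TRUE)
}

read_stl_binary_tris <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nfac <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(nfac) != 1L || is.na(nfac) || nfac <= 0L) {
    abort_format(sprintf("'%s': empty facet list", path))
  }
  rec <- readBin(con, "raw", n = nfac * 50L)
  if (length(rec) != nfac * 50L) {
    abort_format(sprintf("'%s': truncated at facet record %d", path,
                         length(rec) %/% 50L + 1L))
  }
  idx <- rep(seq(0L, by = 50L, length.out = nfac), each = 36L) +
    rep(13:48, times = nfac)
  vals <- readBin(rec[idx], "double", n = nfac * 9L, size = 4L, endian = "little")
  m <- matrix(vals, ncol = 9L, byrow = TRUE)
  matrix(t(m), ncol = 3L, byrow = TRUE)
}

weld_triangle_soup <- function(tri) {
  key <- paste(tri[, 1L], tri[, 2L], tri[, 3L], sep = "/")
  first <- !duplicated(key)
  verts <- tri[first, , drop = FALSE]
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

fmt_num <- function(x) {
  # Shortest decimal round-trip representation keeps files exact and compact.
  formatC(x, format = "g", digits = 17)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  out <- character(2L + 7L * nrow(f))
  out[1L] <- "solid soleusshape"
  pos <- 2L
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    out[pos:(pos + 6L)] <- c(
      sprintf("  facet normal %s %s %s", fmt_num(nrm[i, 1L]), fmt_num(nrm[i, 2L]), fmt_num(nrm[i, 3L])),
      "    outer loop",
      sprintf("      vertex %s %s %s", fmt_num(tri[1L, 1L]), fmt_num(tri[1L, 2L]), fmt_num(tri[1L, 3L])),
      sprintf("      vertex %s %s %s", fmt_num(tri[2L, 1L]), fmt_num(tri[2L, 2L]), fmt_num(tri[2L, 3L])),
      sprintf("      vertex %s %s %s", fmt_num(tri[3L, 1L]), fmt_num(tri[3L, 2L]), fmt_num(tri[3L, 3L])),
      "    endloop",
      "  endfacet")
    pos <- pos + 7L
  }
  out[pos] <- "endsolid soleusshape"
  writeLines(out, path)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "soleusshape binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  zero2 <- as.raw(c(0L, 0L))
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    e1 <- tri[2L, ] - tri[1L, ]; e2 <- tri[3L, ] - tri[1L, ]
    nrm <- cross3(e1, e2)
    len <- sqrt(sum(nrm^2)); if (len > 0) nrm <- nrm / len
    writeBin(as.numeric(c(nrm, t(tri))), con, size = 4L, endian = "little")
    writeBin(zero2, con)
  }
}

# --- PLY (ASCII) -------------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply") {
    abort_format(sprintf("'%s' is not a PLY file", path))
  }
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) abort_format(sprintf("'%s': missing end_header", path))
  hdr <- trimws(lines[seq_len(hdr_end)])
  nvert <- nface <- NA_integer_
  vprops <- character()
  element <- ""
  for (h in hdr) {
    tok <- strsplit(h, "\\s+")[[1L]]
    if (tok[1L] == "format" && tok[2L] != "ascii") {
      abort_unsupported(sprintf("'%s': only ASCII PLY is supported", path))
    }
    if (tok[1L] == "element") {
      element <- tok[2L]
      if (element == "vertex") nvert <- as.integer(tok[3L])
      if (element == "face") nface <- as.integer(tok[3L])
    }
    if (tok[1L] == "property" && element == "vertex" && tok[2L] != "list") {
      vprops <- c(vprops, tok[3L])
    }
  }
  if (is.na(nvert) || is.na(nface) || nvert < 1L || nface < 1L) {
    abort_format(sprintf("'%s': missing vertex or face element", path))
  }
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vdat <- strsplit(trimws(body[seq_len(nvert)]), "\\s+")
  vm <- matrix(suppressWarnings(as.numeric(unlist(vdat))), nrow = nvert,
               byrow = TRUE)
  ix <- match(c("x", "y", "z"), vprops)
  if (any(is.na(ix))) abort_format(sprintf("'%s': vertex element lacks x/y/z", path))
  verts <- vm[, ix, drop = FALSE]
  fdat <- strsplit(trimws(body[nvert + seq_len(nface)]), "\\s+")
  faces <- t(vapply(fdat, function(tok) {
    cnt <- as.integer(tok[1L])
    if (cnt != 3L) abort_format(sprintf("'%s': non-triangular face", path))
    as.integer(tok[2:4]) + 1L
  }, integer(3L)))
  mesh <- surface_mesh(verts, faces)
  qix <- match("quality", vprops)
  if (!is.na(qix)) attr(mesh, "scalars") <- vm[, qix]
  mesh
}

write_ply <- function(mesh, path, scalars = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           if (!is.null(scalars)) "property float quality",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  vlines <- if (is.null(scalars)) {
    paste(fmt_num(v[, 1L]), fmt_num(v[, 2L]), fmt_num(v[, 3L]))
  } else {
    paste(fmt_num(v[, 1L]), fmt_num(v[, 2L]), fmt_num(v[, 3L]), fmt_num(scalars))
  }
  flines <- paste(3L, f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
  writeLines(c(hdr, vlines, flines), path)
}
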
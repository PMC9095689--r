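test_that("STL and PLY writers round-trip meshes exactly", {
  tet <- tetra_mesh()
  for (case in list(list(fmt = "stl", binary = FALSE),
                    list(fmt = "stl", binary = TRUE),
                    list(fmt = "ply", binary = FALSE))) {
    path <- withr::local_tempfile(fileext = paste0(".", case$fmt))
    write_mesh(tet, path, format = case$fmt, binary = case$binary)
    back <- read_mesh(path)
    # STL welds a facet soup, so vertex order may change; compare as sets of
    # faces with resolved coordinates
    face_key <- function(m) {
      sort(apply(m$faces, 1L, function(f) {
        paste(sort(apply(m$vertices[f, , drop = FALSE], 1L, paste, collapse = ",")),
              collapse = ";")
      }))
    }
    expect_equal(face_key(back), face_key(tet))
    expect_equal(nrow(back$vertices), 4L)
  }
})

test_that("both STL dialects written by an independent tool parse identically", {
  dir <- withr::local_tempdir()
  script <- file.path(dir, "gen.py")
  writeLines(c(
    "import trimesh, numpy as np, sys",
    "m = trimesh.Trimesh(vertices=[[0,0,0],[1,0,0],[0,1,0],[0,0,1]],",
    "                    faces=[[0,2,1],[0,1,3],[0,3,2],[1,2,3]], process=False)",
    sprintf("open('%s/bin.stl','wb').write(trimesh.exchange.stl.export_stl(m))", dir),
    sprintf("open('%s/asc.stl','w').write(trimesh.exchange.stl.export_stl_ascii(m))", dir)
  ), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  a <- read_mesh(file.path(dir, "asc.stl"))
  b <- read_mesh(file.path(dir, "bin.stl"))
  expect_equal(nrow(a$vertices), 4L)
  ord <- function(m) m$vertices[order(m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), ]
  expect_equal(ord(a), ord(b))
  expect_equal(nrow(a$faces), nrow(b$faces))
})

test_that("malformed geometry raises format errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid bad", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 nan", "      vertex 1 0 0", "      vertex 0 1 0",
               "    endloop", "  endfacet", "endsolid bad"), path)
  expect_error(read_mesh(path), class = "soleusshape_error_format")

  empty <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid nothing", "endsolid nothing"), empty)
  expect_error(read_mesh(empty), class = "soleusshape_error_format")

  expect_error(read_mesh(file.path(tempdir(), "does-not-exist.stl")),
               class = "soleusshape_error_io")
})

test_that("PLY stores and recovers per-vertex scalars; STL refuses them", {
  tet <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".ply")
  sc <- c(0, 0.5, 1.25, 0)
  write_mesh(tet, path, scalars = sc)
  back <- read_mesh(path)
  expect_equal(attr(back, "scalars"), sc)
  expect_mesh_equal(back, tet)

  write_mesh(tet, path, scalars = rep(0, 4))
  expect_equal(attr(read_mesh(path), "scalars"), rep(0, 4))

  expect_error(write_mesh(tet, withr::local_tempfile(fileext = ".stl"),
                          scalars = sc),
               class = "soleusshape_error_unsupported")
  expect_error(write_mesh(tet, path, scalars = c(1, 2)),
               class = "soleusshape_error_dimension")
})

test_that("shape-vector flattening is vertex-major and invertible", {
  tet <- tetra_mesh()
  v <- mesh_to_shape_vector(tet)
  expect_equal(as.numeric(v)[1:6], c(0, 0, 0, 1, 0, 0))
  expect_equal(length(v), 12L)
  back <- shape_vector_to_mesh(v, tet$faces)
  expect_mesh_equal(back, tet)
  expect_error(shape_vector_to_mesh(v, rbind(c(1, 2, 9))),
               class = "soleusshape_error_dimension")
})

test_that("mesh invariants are enforced at construction", {
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            rbind(c(1, 2, 3))),
               class = "soleusshape_error_format")   # n >= 4
  v <- tetra_mesh()$vertices
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))),
               class = "soleusshape_error_format")   # degenerate face
  expect_error(surface_mesh(v, rbind(c(1, 2, 5))),
               class = "soleusshape_error_format")   # out of range
})

test_that("sagittal reflection is an involution that preserves geometry", {
  tpl <- base_soleus_template(6)
  refl <- reflect_sagittal(tpl)
  expect_equal(mean(refl$vertices[, 1]), -mean(tpl$vertices[, 1]))
  expect_mesh_equal(reflect_sagittal(refl), tpl)
  # winding fixed: enclosed volume keeps its sign
  expect_equal(mesh_volume(refl), mesh_volume(tpl), tolerance = 1e-12)
  # pairwise distances preserved (isometry) on a vertex subset
  idx <- c(1, 5, 20, 40)
  expect_equal(as.matrix(dist(refl$vertices[idx, ])),
               as.matrix(dist(tpl$vertices[idx, ])), tolerance = 1e-12)
})
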
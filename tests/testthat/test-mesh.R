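test_that("unit cube STL round-trip preserves the 1 mm^3 volume exactly", {
  m <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), 1.0)
  f <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, f)
  m2 <- read_mesh(f)
  expect_equal(mesh_volume(m2), 1.0)
  expect_identical(nrow(m2$faces), nrow(m$faces))
})

test_that("PLY round-trip preserves volume within 1e-9 relative", {
  m <- icosphere(radius = 7.3, center = c(2.5, -1, 4), subdivisions = 3)
  f <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, f)
  m2 <- read_mesh(f)
  expect_identical(nrow(m2$vertices), nrow(m$vertices))
  expect_lt(abs(mesh_volume(m2) - mesh_volume(m)) / mesh_volume(m), 1e-9)
})

test_that("degenerate mesh files are rejected or flagged, not repaired", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property double x", "property double y", "property double z",
               "element face 0",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0"), f)
  expect_error(read_mesh(f), "no faces")
  # a single open triangle is non-manifold: flagged with a warning
  tri <- structure(list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        faces = matrix(c(1L, 2L, 3L), 1), provenance = NULL),
                   class = "triangle_mesh")
  f2 <- withr::local_tempfile(fileext = ".stl")
  graftmorph:::.write_stl(tri, f2)
  expect_warning(read_mesh(f2), "not manifold")
})

test_that("mesh_volume matches analytic solids and is rigid-motion invariant", {
  # icosphere at 4 subdivisions: within 0.5% of 4/3 pi r^3
  s <- icosphere(radius = 10, subdivisions = 4)
  expect_lt(abs(mesh_volume(s) - 4188.790) / 4188.790, 0.005)
  shifted <- s
  shifted$vertices <- sweep(s$vertices, 2, c(123.4, -56.7, 89.1), `+`)
  expect_lt(abs(mesh_volume(shifted) - mesh_volume(s)) / mesh_volume(s), 1e-9)
  tf <- rigid_transform(graftmorph:::.axis_angle(c(1, 2, 3), 37),
                        c(5, -4, 18))
  expect_lt(abs(mesh_volume(apply_transform(s, tf)) - mesh_volume(s)) /
              mesh_volume(s), 1e-9)
})

test_that("volumetry refuses non-watertight meshes, naming the defect", {
  m <- icosphere(radius = 5, subdivisions = 2)
  m$faces <- m$faces[-1, , drop = FALSE]
  expect_false(is_watertight(m))
  expect_error(mesh_volume(m), "boundary")
})

test_that("inward-wound meshes are flipped to outward with a notice", {
  m <- box_mesh()
  inverted <- m$faces[, c(1, 3, 2)]
  expect_message(m2 <- triangle_mesh(m$vertices, inverted), "flipping")
  expect_equal(mesh_volume(m2), 1.0)
})

test_that("mesh components split and keep watertight pieces", {
  a <- icosphere(3, c(0, 0, 0), 1)
  b <- icosphere(2, c(20, 0, 0), 1)
  merged <- triangle_mesh(rbind(a$vertices, b$vertices),
                          rbind(a$faces, b$faces + nrow(a$vertices)))
  comps <- mesh_components(merged)
  expect_length(comps, 2)
  expect_lt(abs(mesh_volume(comps[[1]]) - mesh_volume(a)) / mesh_volume(a),
            1e-9)
})
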
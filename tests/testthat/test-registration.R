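test_that("moment initialization is exact for self- and translated pairs", {
  m <- coarse_preop_mesh()
  tf <- initialize_alignment(m, m)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tf$translation)), 1e-9)
  shifted <- m
  shifted$vertices <- sweep(m$vertices, 2, c(10, -5, 3), `+`)
  tf2 <- initialize_alignment(m, shifted)
  expect_lt(max(abs(tf2$translation - c(10, -5, 3))), 1e-6)
  expect_lt(rotation_angle_deg(tf2), 1e-4)   # eigen jitter only
})

test_that("moment initialization lands within 10 degrees for rotated bones", {
  m <- coarse_preop_mesh()
  set.seed(5)
  tru <- rigid_transform(graftmorph:::.axis_angle(rnorm(3), 25), c(4, 2, -6))
  init <- initialize_alignment(m, apply_transform(m, tru))
  err <- compose_transform(invert_transform(tru), init)
  expect_lt(rotation_angle_deg(err), 10)
})

test_that("ICP of a mesh onto itself is the identity", {
  m <- coarse_preop_mesh()
  res <- icp_register(m, m, init = rigid_transform(), multi_start = FALSE)
  expect_true(res$converged)
  expect_lt(res$rms_residual, 1e-6)
  expect_lt(rotation_angle_deg(res$transform), 1e-4)
})

test_that("ICP recovers a known rigid transform (15 deg, 8 mm)", {
  m <- coarse_preop_mesh()
  tru <- rigid_transform(graftmorph:::.axis_angle(c(1, 2, 0.5), 15),
                         8 * c(1, 1, 1) / sqrt(3))
  res <- icp_register(m, apply_transform(m, tru))
  err <- compose_transform(invert_transform(tru), res$transform)
  expect_lt(rotation_angle_deg(err), 0.5)
  expect_lt(sqrt(sum(err$translation^2)), 0.2)
})

test_that("two-pass registration copes with partial overlap and vertex noise", {
  m <- coarse_preop_mesh()
  # follow-up bone without the harvested coracoid: cut it off
  plane <- phantom_osteotomy_plane(coarse_spec())
  fixed_base <- cut_mesh(m, plane)$remainder
  set.seed(8)
  tru <- rigid_transform(graftmorph:::.axis_angle(rnorm(3), 12), c(5, -7, 3))
  fixed <- apply_transform(fixed_base, tru)
  fixed$vertices <- fixed$vertices + matrix(rnorm(length(fixed$vertices), 0, 0.3),
                                            ncol = 3)
  res <- suppressWarnings(register_scapula_pair(m, fixed, plane = plane))
  err <- compose_transform(invert_transform(tru), res$transform)
  expect_lt(rotation_angle_deg(err), 2)
  # the refinement pass must improve on the one-pass trimmed fit
  one <- suppressWarnings(icp_register(m, fixed))
  err1 <- compose_transform(invert_transform(tru), one$transform)
  expect_lte(rotation_angle_deg(err), rotation_angle_deg(err1))
})

test_that("rigid transforms preserve volume and compose with inverses", {
  s <- icosphere(6, c(1, 2, 3), 3)
  tf <- rigid_transform(graftmorph:::.axis_angle(c(0.2, 1, -0.4), 73),
                        c(12, -8, 5))
  expect_lt(abs(mesh_volume(apply_transform(s, tf)) - mesh_volume(s)) /
              mesh_volume(s), 1e-9)
  id <- compose_transform(tf, invert_transform(tf))
  expect_lt(rotation_angle_deg(id), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
  expect_identical(apply_transform(s, rigid_transform())$vertices, s$vertices)
})

test_that("registration is equivariant under pre-transforms of the moving mesh", {
  m <- coarse_preop_mesh()
  fixed <- apply_transform(m, rigid_transform(
    graftmorph:::.axis_angle(c(0, 0, 1), 10), c(3, 1, -2)))
  base <- icp_register(m, fixed)
  pre <- rigid_transform(graftmorph:::.axis_angle(c(1, 0, 0), 8), c(-4, 2, 6))
  res2 <- icp_register(apply_transform(m, pre), fixed)
  # result2 should equal base composed with pre^{-1}
  expected <- compose_transform(base$transform, invert_transform(pre))
  err <- compose_transform(invert_transform(expected), res2$transform)
  expect_lt(rotation_angle_deg(err), 0.5)
  expect_lt(sqrt(sum(err$translation^2)), 0.3)
})

test_that("rigid_transform rejects reflections", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "reflection|det")
})

test_that("transform JSON serialization round-trips", {
  tf <- rigid_transform(graftmorph:::.axis_angle(c(1, 1, 1), 30), c(1, 2, 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(tf, f, metadata = list(rms = 0.1))
  tf2 <- read_transform(f)
  expect_lt(max(abs(tf2$rotation - tf$rotation)), 1e-12)
  expect_lt(max(abs(tf2$translation - tf$translation)), 1e-12)
})
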
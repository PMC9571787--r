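test_that("bone segmentation recovers an analytic solid within 3%", {
  v <- digital_sphere_volume(10, spacing = 1, value = 700)
  m <- segment_bone(v, segmentation_params())
  vol <- sum(m$data) * voxel_volume(m)
  expect_lt(abs(vol - 4188.79) / 4188.79, 0.03)
})

test_that("an all-zero volume raises an explicit empty-segmentation error", {
  v <- ct_volume(array(0, c(16, 16, 16)), rep(1, 3))
  expect_error(segment_bone(v), "empty bone segmentation")
  expect_error(segment_bone(v), "226")   # error names the thresholds
})

test_that("screw voxels are excluded from the bone mask by the upper bound", {
  ph <- coarse_phantom(frac = 0)
  bone <- segment_bone(ph$followup, segmentation_params())
  metal_truth <- ph$followup$data >= 2000
  expect_false(any(bone$data & metal_truth))
})

test_that("bone and metal masks are disjoint for arbitrary volumes", {
  set.seed(42)
  v <- ct_volume(array(sample(c(0, 700, 3000), 18^3, replace = TRUE,
                              prob = c(0.5, 0.4, 0.1)), c(18, 18, 18)),
                 rep(1, 3))
  p <- segmentation_params(min_component_voxels = 1, closing_radius = 0)
  b <- segment_bone(v, p)
  m <- suppressWarnings(segment_metal(v, p))
  expect_false(any(b$data & m$data))
})

test_that("metal segmentation finds the two screws with analytic volumes", {
  # two cylinders at 3000 HU in an empty volume (r = 2.25 mm, L = 20 mm)
  n <- c(80, 40, 72); sp <- 0.375
  idx <- arrayInd(seq_len(prod(n)), n) - 1
  p <- idx * sp
  in_cyl <- function(y0, z0) {
    (p[, 2] - y0)^2 + (p[, 3] - z0)^2 <= 2.25^2 & p[, 1] >= 5 & p[, 1] <= 25
  }
  v <- ct_volume(array((in_cyl(10, 10) | in_cyl(10, 20)) * 3000, n),
                 rep(sp, 3))
  m <- segment_metal(v, segmentation_params())
  expect_identical(attr(m, "n_components"), 2L)
  lab <- array(graftmorph:::cpp_label3d(m$data, as.integer(dim(m$data))),
               dim(m$data))
  analytic <- pi * 2.25^2 * 20
  for (k in 1:2) {
    vol <- sum(lab == k) * voxel_volume(m)
    expect_lt(abs(vol - analytic) / analytic, 0.05)
  }
})

test_that("metal segmentation warns when screws are absent", {
  ph <- coarse_phantom(frac = 0)
  expect_warning(m <- segment_metal(ph$preop, segmentation_params()),
                 "absent")
  expect_identical(sum(m$data), 0L)
  v <- digital_sphere_volume(8, spacing = 1, value = 700)
  expect_warning(m2 <- segment_metal(v), "absent")
  expect_identical(sum(m2$data), 0L)
})

test_that("segmentation is deterministic, bit for bit", {
  ph <- coarse_phantom(frac = 0.2)
  a <- segment_bone(ph$followup, segmentation_params())
  b <- segment_bone(ph$followup, segmentation_params())
  expect_identical(a$data, b$data)
})

test_that("extracted surfaces are watertight with voxel-accurate volumes", {
  # solid 10x10x10 voxel cube at 1 mm spacing
  a <- array(FALSE, c(14, 14, 14)); a[3:12, 3:12, 3:12] <- TRUE
  cube <- extract_surface(binary_mask(a, rep(1, 3)))
  expect_true(is_watertight(cube))
  expect_lt(abs(mesh_volume(cube) - 1000) / 1000, 0.05)
  # single voxel: a minimal closed solid
  b <- array(FALSE, c(5, 5, 5)); b[3, 3, 3] <- TRUE
  single <- extract_surface(binary_mask(b, rep(1, 3)))
  expect_true(is_watertight(single))
  expect_gt(mesh_volume(single), 0)
})

test_that("digital-sphere mesh volume converges with radius", {
  err <- vapply(c(5, 10, 20), function(r) {
    v <- digital_sphere_volume(r, spacing = 1)
    mask <- binary_mask(v$data > 350, v$spacing, v$origin)
    vol_vox <- sum(mask$data) * voxel_volume(mask)
    abs(mesh_volume(extract_surface(mask)) - vol_vox) / vol_vox
  }, numeric(1))
  expect_lt(err[2], 0.03)   # 10 mm sphere within 3% of the voxel count
  expect_lt(err[3], err[1]) # error shrinks as the solid grows
  v10 <- digital_sphere_volume(10, spacing = 1)
  mask10 <- binary_mask(v10$data > 350, v10$spacing, v10$origin)
  expect_lt(abs(mesh_volume(extract_surface(mask10)) - 4188.79) / 4188.79,
            0.03)
})
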
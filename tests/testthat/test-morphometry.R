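test_that("cutting a unit cube at its mid-plane yields two watertight halves", {
  cube <- box_mesh()
  cut <- cut_mesh(cube, osteotomy_plane(c(0.5, 0.5, 0.5), c(1, 0, 0)))
  expect_true(is_watertight(cut$graft))
  expect_true(is_watertight(cut$remainder))
  expect_equal(mesh_volume(cut$graft), 0.5, tolerance = 1e-12)
  expect_equal(mesh_volume(cut$remainder), 0.5, tolerance = 1e-12)
})

test_that("a plane missing the mesh returns it untouched with a warning", {
  cube <- box_mesh()
  expect_warning(cut <- cut_mesh(cube, osteotomy_plane(c(5, 0, 0), c(1, 0, 0))),
                 "does not intersect")
  expect_true(is_empty_mesh(cut$graft))
  expect_equal(mesh_volume(cut$remainder), 1.0)
})

test_that("plane cuts conserve volume over random orientations", {
  set.seed(14)
  solids <- list(icosphere(8, c(0, 0, 0), 3), box_mesh(c(-3, -2, -5), c(4, 6, 2)))
  for (i in 1:20) {
    m <- solids[[1 + i %% 2]]
    pl <- osteotomy_plane(colMeans(m$vertices) + rnorm(3, 0, 2), rnorm(3))
    cut <- suppressWarnings(cut_mesh(m, pl))
    total <- mesh_volume(m)
    got <- mesh_volume(cut$graft) + mesh_volume(cut$remainder)
    expect_lt(abs(got - total) / total, 1e-6)
  }
})

test_that("the virtual osteotomy reproduces the phantom graft volume", {
  ph <- coarse_phantom(frac = 0)
  spec <- coarse_spec()
  mesh <- coarse_preop_mesh()
  cut <- cut_mesh(mesh, phantom_osteotomy_plane(spec))
  # analytic frustum volume of the distal coracoid segment
  rb <- spec$coracoid_radius_base; tp <- spec$coracoid_taper
  r1 <- rb - tp * spec$osteotomy_offset
  r2 <- rb - tp * spec$coracoid_length
  L <- spec$coracoid_length - spec$osteotomy_offset
  analytic <- pi * L / 3 * (r1^2 + r1 * r2 + r2^2)
  expect_lt(abs(mesh_volume(cut$graft) - analytic) / analytic, 0.03)
})

test_that("resorption metrics follow the definition, including the published pair", {
  r <- compute_resorption(2931, 2010)
  expect_equal(r$resorption_mm3, 921)
  expect_equal(r$resorption_pct, 100 * 921 / 2931, tolerance = 1e-12)
  r0 <- compute_resorption(100, 100)
  expect_equal(r0$resorption_mm3, 0)
  expect_equal(r0$resorption_pct, 0)
  r2 <- compute_resorption(2724, 2369)
  expect_equal(r2$resorption_mm3, 355)
  expect_equal(r2$resorption_pct, 13.03, tolerance = 1e-3)
  # growth is allowed (negative resorption), zero baseline is not
  expect_lt(compute_resorption(100, 120)$resorption_pct, 0)
  expect_error(compute_resorption(0, 10), "undefined")
})

test_that("regional resorption is 0% for identical meshes, 100% for nothing", {
  g <- icosphere(6, c(0, 0, 0), 3)
  same <- regional_resorption(g, g)
  expect_true(all(same < 1e-9))
  gone <- regional_resorption(g, NULL)
  expect_true(all(gone == 100))
})

test_that("regional map localizes superior-only resorption", {
  # pure superior gradient, surface weighting off
  ph <- coarse_phantom(frac = 0.3, seed = 21, gradient_weight = 1)
  p <- segmentation_params()
  t0 <- extract_surface(ph$truth$graft_mask_t0, p)
  fu <- extract_surface(ph$truth$graft_mask_followup, p)
  reg <- regional_resorption(t0, fu, ph$truth$axes_followup)
  truth_sup <- 100 * ph$truth$per_region["superior"]
  expect_lt(abs(reg["superior"] - truth_sup), 5)
  expect_lt(reg["inferior"], 5)
})

test_that("Zhu surrogate grades the canonical configurations", {
  sm <- screw_model(axis = c(-1, 0, 0), head_center = c(10, 0, 0),
                    head_radius = 3.2, shaft_radius = 2.25, length = 20,
                    head_length = 3)
  big <- box_mesh(c(-15, -10, -10), c(14, 10, 10))   # buries the whole screw
  expect_identical(zhu_grade(big, list(sm))$overall, 0L)
  empty <- structure(list(vertices = matrix(numeric(0), 0, 3),
                          faces = matrix(integer(0), 0, 3), provenance = NULL),
                     class = "triangle_mesh")
  expect_identical(zhu_grade(empty, list(sm))$overall, 3L)
  # head exposed, shaft covered: graft stops short of the head
  shaft_only <- box_mesh(c(-15, -10, -10), c(7, 10, 10))
  expect_identical(zhu_grade(shaft_only, list(sm))$overall, 1L)
  # graft remains near the shaft but covers little of it
  crumb <- box_mesh(c(-15, -10, -10), c(-8, 10, 10))
  expect_identical(zhu_grade(crumb, list(sm))$overall, 2L)
  # overall is the max over screws; fit failures are ungradable
  two <- zhu_grade(shaft_only, list(sm, NULL))
  expect_identical(two$overall, 1L)
  expect_true(is.na(two$per_screw[2]))
  g <- zhu_grade(empty, list(sm, sm))
  expect_identical(g$overall, max(g$per_screw))
})

test_that("graft placement is the identity when already in place", {
  ph <- coarse_phantom(frac = 0)
  g <- extract_surface(ph$truth$graft_mask_t0, segmentation_params())
  placed <- place_graft(g, NULL, g,
                        superior_axis = ph$truth$axes_followup[1, ])
  tf <- attr(placed, "transform")
  expect_lt(rotation_angle_deg(tf), 1e-4)
  expect_lt(sqrt(sum(tf$translation^2)), 1e-4)
})

test_that("inferior anchoring tolerates superiorly concentrated resorption", {
  ph <- coarse_phantom(frac = 0.3, seed = 21, gradient_weight = 1)
  p <- segmentation_params()
  t0 <- extract_surface(ph$truth$graft_mask_t0, p)
  fu <- extract_surface(ph$truth$graft_mask_followup, p)
  # displace the modeled graft, then let inferior anchoring bring it home
  off <- rigid_transform(graftmorph:::.axis_angle(c(0, 1, 0), 10), c(6, -4, 8))
  moved <- apply_transform(t0, off)
  placed <- place_graft(moved, NULL, fu,
                        superior_axis = ph$truth$axes_followup[1, ])
  # recovered pose should invert the displacement
  err <- compose_transform(attr(placed, "transform"), off)
  expect_lt(rotation_angle_deg(err), 3)
  expect_lt(sqrt(sum(err$translation^2)), 1.2)
})

test_that("isolation flags total graft loss as a grade-III candidate", {
  ph <- coarse_phantom(frac = 1)
  p <- segmentation_params()
  bone_fu <- segment_bone(ph$followup, p)
  pre <- apply_transform(coarse_preop_mesh(), ph$truth$interscan_transform)
  metal <- segment_metal(ph$followup, p)
  iso <- isolate_followup_graft(bone_fu, pre, metal, params = p)
  expect_true(is_empty_mesh(iso))
  expect_true(attr(iso, "grade3_candidate"))
})
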
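test_that("phantom generation is deterministic for a fixed seed", {
  a <- generate_phantom_pair(coarse_spec(frac = 0.2, seed = 13))
  b <- generate_phantom_pair(coarse_spec(frac = 0.2, seed = 13))
  expect_identical(a$preop$data, b$preop$data)
  expect_identical(a$followup$data, b$followup$data)
  expect_identical(a$truth$graft_volume_followup, b$truth$graft_volume_followup)
})

test_that("zero resorption means identical truth volumes", {
  ph <- coarse_phantom(frac = 0)
  expect_identical(ph$truth$graft_volume_t0, ph$truth$graft_volume_followup)
  expect_identical(ph$truth$resorbed_fraction, 0)
  expect_identical(ph$truth$expected_zhu_grade, 0L)
})

test_that("truth volumes are exact voxel counts and noise never changes them", {
  ph <- coarse_phantom(frac = 0.25, seed = 4)
  vox <- coarse_spec()$voxel_spacing^3
  n_t0 <- ph$truth$graft_volume_t0 / vox
  expect_equal(n_t0, round(n_t0), tolerance = 1e-9)
  quiet <- generate_phantom_pair(coarse_spec(frac = 0.25, seed = 4,
                                             noise_sigma = 0))
  loud <- generate_phantom_pair(coarse_spec(frac = 0.25, seed = 4,
                                            noise_sigma = 60))
  expect_identical(quiet$truth$graft_volume_followup,
                   loud$truth$graft_volume_followup)
  expect_identical(quiet$truth$expected_zhu_per_screw,
                   loud$truth$expected_zhu_per_screw)
})

test_that("graded osteolysis is strictly monotone in the requested fraction", {
  vols <- vapply(c(0, 0.1, 0.25, 0.4, 0.6, 0.8),
                 function(f) coarse_phantom(frac = f, seed = 9)$truth$graft_volume_followup,
                 numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("the requested resorbed fraction is realized within one percent", {
  for (f in c(0.1, 0.35, 0.6)) {
    ph <- coarse_phantom(frac = f, seed = 2)
    expect_lt(abs(ph$truth$resorbed_fraction - f), 0.01)
  }
})

test_that("a superior gradient concentrates loss in the superior half", {
  ph <- coarse_phantom(frac = 0.3, seed = 21, gradient_weight = 1)
  pr <- ph$truth$per_region
  expect_gt(pr["superior"], pr["inferior"])
  expect_lt(pr["inferior"], 0.05)
  expect_lt(abs(pr["superior"] - 2 * 0.3), 0.08)  # all loss in one half
})

test_that("a graft pose buried in the scapula is rejected", {
  spec <- coarse_spec()
  spec$graft_base <- c(6, 0, -10)   # deep inside the body ellipsoid
  expect_error(generate_phantom_pair(spec), "overlaps the scapula")
})

test_that("phantom cohorts are reproducible and stratified", {
  co1 <- generate_cohort(n_per_grade = c(2, 2, 2), voxel_spacing = 1.5,
                         seed = 6)
  co2 <- generate_cohort(n_per_grade = c(2, 2, 2), voxel_spacing = 1.5,
                         seed = 6)
  expect_identical(co1$table, co2$table)
  expect_identical(nrow(co1$table), 6L)
  # strata means follow the requested ordering
  m <- tapply(co1$table$resorption_pct, co1$table$stratum, mean)
  expect_true(all(diff(m) > 0))
})
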
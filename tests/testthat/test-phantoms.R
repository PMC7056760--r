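test_that("NEMA sphere layout matches the printed diameters and volumes", {
  lay <- nema_sphere_layout()
  expect_equal(lay$diameter_mm, c(10, 13, 17, 22, 28, 37))
  expect_equal(round(lay$volume_ml, 2), c(0.52, 1.15, 2.57, 5.58, 11.49, 26.52),
               tolerance = 1e-2)
  # ring pitch circle
  expect_equal(sqrt(lay$x^2 + lay$y^2), rep(114.4 / 2, 6), tolerance = 1e-9)
})

test_that("NEMA IQ phantom voxelization is faithful", {
  ph <- fixture("nema_fine", make_nema_iq(tc_background = 6, voxel = 2))
  lay <- nema_sphere_layout()
  vox_ml <- prod(ph$voxel_mm) / 1000
  # total Ho activity within 2% of the analytic value at 2-mm voxels
  expect_equal(phantom_total_activity(ph, "Ho166"),
               0.8 * sum(lay$volume_ml), tolerance = 0.02)
  # background compartment volume close to the requested 5.5 L
  bg <- ph$activity_tc > 0
  expect_equal(sum(bg) * vox_ml / 1000, 5.5, tolerance = 0.02)
  # Tc concentration and mutual exclusivity of the compartments
  expect_equal(max(ph$activity_tc), 6e-3, tolerance = 1e-12)
  expect_true(all(ph$activity_tc[ph$activity_ho > 0] == 0))
  # agar region carries no activity
  agar <- ph$materials == 4L
  expect_gt(sum(agar), 0)
  expect_true(all(ph$activity_tc[agar] == 0))
  expect_error(make_nema_iq(voxel = 4), "10-mm sphere")
})

test_that("cylinder phantom matches activity, concentration and volume", {
  ph <- make_cylinder(volume_l = 6.3, tc_activity_mbq = 50, voxel = 2)
  expect_equal(ph$config$tc_conc_mbq_ml * 1000, 50000 / 6300, tolerance = 1e-9)
  expect_equal(phantom_total_activity(ph, "Tc99m"), 50, tolerance = 0.02)
  vox_ml <- prod(ph$voxel_mm) / 1000
  expect_equal(sum(ph$activity_tc > 0) * vox_ml / 1000, 6.3, tolerance = 0.02)
  ph0 <- make_cylinder(tc_activity_mbq = 0, voxel = 4)
  expect_true(all(ph0$activity_tc == 0))
})

test_that("line-source phantom has two PMMA slabs and activity on the line only", {
  ph <- make_line_source_pmma(line_activity_mbq = 50, voxel = 4)
  vox_ml <- prod(ph$voxel_mm) / 1000
  pmma <- ph$materials == 2L
  # two 40 x 40 x 10 cm^3 slabs: 16 litres of PMMA each
  expect_equal(sum(pmma) * vox_ml / 1000, 32, tolerance = 0.03)
  # slabs split symmetrically about the line plane
  co <- duospect:::grid_coords(ph$dim, ph$voxel_mm)
  ix <- which(apply(pmma, 2, any))
  expect_true(any(co[[2]][ix] > 0) && any(co[[2]][ix] < 0))
  expect_equal(phantom_total_activity(ph, "Tc99m"), 50, tolerance = 1e-9)
  act_vox <- which(ph$activity_tc > 0, arr.ind = TRUE)
  expect_equal(length(unique(act_vox[, 1])), 1)   # one voxel wide in x
  expect_equal(length(unique(act_vox[, 2])), 1)   # and in y
  expect_true(all(ph$materials[ph$activity_tc > 0] == 0L))  # line sits in air gap
  # the slab-material toggle changes attenuation along rays through slabs
  phw <- make_line_source_pmma(line_activity_mbq = 50, voxel = 4,
                               slab_material = "water")
  expect_true(all(phw$materials[pmma] == 1L))
  mu_p <- attenuation_coefficient("pmma", 140)
  mu_w <- attenuation_coefficient("water", 140)
  expect_false(isTRUE(all.equal(mu_p, mu_w)))
})

test_that("torso phantom concentrations follow the compartment definitions", {
  ph <- fixture("torso_fine", make_torso(voxel = 2))
  expect_equal(ph$config$insert_conc_mbq_ml, 53 / 130, tolerance = 1e-12)
  expect_equal(round(ph$config$insert_conc_mbq_ml, 1), 0.4)
  expect_equal(phantom_total_activity(ph, "Ho166"), 53, tolerance = 0.03)
  # Tc total at 34 kBq/ml over ~1200 ml (minus the insert's displacement)
  liver_ml <- sum(ph$activity_tc > 0) * prod(ph$voxel_mm) / 1000
  expect_equal(liver_ml, 1200 - 130, tolerance = 0.03)
  expect_equal(max(ph$activity_tc), 0.034, tolerance = 1e-12)
  # no Tc outside the liver, no Ho outside the insert
  expect_true(all(ph$activity_ho[ph$activity_tc > 0] == 0))
  expect_equal(sum(ph$activity_ho > 0) * prod(ph$voxel_mm) / 1000, 130,
               tolerance = 0.05)
})

test_that("voxelized totals converge to analytic values as voxels shrink", {
  err <- vapply(c(4, 2, 1), function(v) {
    ph <- make_cylinder(volume_l = 1, tc_activity_mbq = 10, voxel = v,
                        diameter_mm = 120)
    abs(phantom_total_activity(ph, "Tc99m") - 10) / 10
  }, numeric(1))
  expect_lt(err[2], 0.02)
  expect_lt(err[3], 0.01)
})

test_that("phantom generation is deterministic and resampling conserves activity", {
  a <- suppressWarnings(make_nema_iq(tc_background = 6, voxel = 4.8 * 0.6))
  b <- suppressWarnings(make_nema_iq(tc_background = 6, voxel = 4.8 * 0.6))
  expect_identical(a$activity_ho, b$activity_ho)
  expect_identical(a$materials, b$materials)
  rs <- resample_phantom(a, 4.8)
  expect_equal(phantom_total_activity(rs, "Ho166"),
               phantom_total_activity(a, "Ho166"), tolerance = 0.05)
  expect_equal(phantom_total_activity(rs, "Tc99m"),
               phantom_total_activity(a, "Tc99m"), tolerance = 0.05)
})
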
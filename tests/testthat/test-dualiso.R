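dual_setup <- function() {
  fixture("dual_setup", {
    ph <- tiny_phantom(24, 16, voxel = 9.6)
    ph$activity_ho[10:14, 10:14, 7:10] <- 0.5
    geom <- acquisition_geometry(n_angles = 16, nu = 24, nv = 16,
                                 pitch_mm = 9.6)
    tabs <- lapply(geom$windows, function(w)
      generate_psf_table(w, pitch_mm = 9.6, max_half = 12))
    list(ph = ph, geom = geom, tabs = tabs)
  })
}

test_that("a study without all four windows is rejected", {
  s <- dual_setup()
  proj <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 2000,
                               seed = 1)
  broken <- proj; broken$counts$sc118 <- NULL
  expect_error(dual_study(broken, s$ph, s$tabs), "sc118")
  st <- dual_study(proj, s$ph, s$tabs)
  expect_s3_class(st, "dual_study")
})

test_that("Ho self-scatter estimate isolates the expected pathways", {
  s <- dual_setup()
  img <- s$ph$activity_ho
  # photopeak-line-only spectrum in vacuum: nothing but unscattered primaries,
  # which the estimate excludes by construction
  ph_air <- s$ph; ph_air$materials[] <- 0L
  sp_line <- emission_spectrum("Ho166", continuum = FALSE, lines = 80.57)
  e_air <- ho_self_scatter_estimate(img, ph_air, s$geom, s$tabs,
                                    n_histories = 4000, seed = 2,
                                    spectrum = sp_line)
  # in water the same spectrum leaves in-phantom scatter only
  e_w <- ho_self_scatter_estimate(img, s$ph, s$geom, s$tabs,
                                  n_histories = 4000, seed = 2,
                                  spectrum = sp_line)
  expect_gt(sum(e_w$counts), 0)
  # in air only the vanishingly rare air scatter remains
  expect_lt(sum(e_air$counts), 1e-2 * sum(e_w$counts))
  # adding the 1379-keV line strictly increases the 81-keV estimate
  sp_two <- emission_spectrum("Ho166", continuum = FALSE,
                              lines = c(80.57, 1379.4))
  e_two <- ho_self_scatter_estimate(img, s$ph, s$geom, s$tabs,
                                    n_histories = 4000, seed = 2,
                                    spectrum = sp_two)
  expect_gt(sum(e_two$counts), sum(e_w$counts))
  # linear in the Ho image at fixed seed
  e1 <- ho_self_scatter_estimate(img, s$ph, s$geom, s$tabs,
                                 n_histories = 4000, seed = 3)
  e2 <- ho_self_scatter_estimate(2 * img, s$ph, s$geom, s$tabs,
                                 n_histories = 4000, seed = 3)
  expect_equal(sum(e2$counts) / sum(e1$counts), 2, tolerance = 1e-9)
  # zero image shortcut
  e0 <- ho_self_scatter_estimate(0 * img, s$ph, s$geom, s$tabs,
                                 n_histories = 100, seed = 3)
  expect_true(all(e0$counts == 0))
})

test_that("Tc background only adds raw counts in the 81-keV window", {
  s <- dual_setup()
  p_ho <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 5000,
                               seed = 6)
  ph_tc <- s$ph; ph_tc$activity_tc[8:16, 8:16, 6:11] <- 0.05
  p_both <- simulate_projections(ph_tc, s$geom, s$tabs, n_histories = 5000,
                                 seed = 6)
  expect_gt(sum(p_both$counts$ho81), sum(p_ho$counts$ho81))
})

test_that("the dual pipeline is deterministic under fixed seeds", {
  s <- dual_setup()
  ph <- s$ph; ph$activity_tc[8:16, 8:16, 6:11] <- 0.05
  proj <- simulate_projections(ph, s$geom, s$tabs, n_histories = 5000,
                               seed = 4, poisson = TRUE)
  cfg <- recon_config(2, n_subsets = 4)
  st <- dual_study(proj, ph, s$tabs, tc_cfg = cfg, ho_cfg = cfg,
                   n_histories = 3000)
  r1 <- reconstruct_dual(st)
  r2 <- reconstruct_dual(st)
  expect_identical(r1$tc_image$data, r2$tc_image$data)
  expect_identical(r1$ho_image$data, r2$ho_image$data)
})

test_that("with empty Tc windows the dual result collapses to the Ho-only reconstruction", {
  s <- dual_setup()
  proj <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 5000,
                               seed = 5)
  # a Tc-free, crosstalk-free acquisition: the Tc-path windows are empty
  for (w in c("sc118", "tc140", "sc170")) proj$counts[[w]][] <- 0
  cfg <- recon_config(3, n_subsets = 4)
  st <- dual_study(proj, s$ph, s$tabs, tc_cfg = cfg, ho_cfg = cfg,
                   n_histories = 3000)
  dual <- reconstruct_dual(st)
  ho_only <- reconstruct_ho_only(st)
  expect_equal(sum(dual$tc_image$data), 0, tolerance = 1e-12)
  expect_true(all(dual$intermediates$downscatter$counts == 0))
  expect_equal(dual$ho_image$data, ho_only$ho_image$data, tolerance = 1e-12)
})

test_that("the downscatter estimate concentrates over the Tc-bearing region", {
  s <- dual_setup()
  ph <- s$ph
  ph$activity_ho[] <- 0
  ph$activity_tc[6:10, 6:10, 6:11] <- 0.1   # off-center Tc blob
  d <- simulate_downscatter(ph$activity_tc, ph, s$geom, s$tabs,
                            n_histories = 8000, seed = 7)
  img <- d$counts[, , 1]
  # center of mass of the angle-0 downscatter sits on the blob's side
  com_u <- sum(rowSums(img) * seq_len(nrow(img))) / sum(img)
  expect_lt(com_u, (nrow(img) + 1) / 2)
  expect_gt(sum(img), 0)
})
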
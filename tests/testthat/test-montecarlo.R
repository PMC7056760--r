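small_mc_setup <- function() {
  fixture("mc_setup", {
    ph <- tiny_phantom(16, 16, voxel = 9.6)
    ph$activity_tc[8, 8, 8] <- 1
    geom <- acquisition_geometry(n_angles = 6, nu = 16, nv = 16,
                                 pitch_mm = 9.6)
    tabs <- lapply(geom$windows, function(w)
      generate_psf_table(w, pitch_mm = 9.6, max_half = 12))
    list(ph = ph, geom = geom, tabs = tabs)
  })
}

test_that("projection simulation handles empty phantoms and is reproducible", {
  s <- small_mc_setup()
  empty <- tiny_phantom(16, 16, voxel = 9.6)
  expect_warning(p0 <- simulate_projections(empty, s$geom, s$tabs,
                                            n_histories = 100, seed = 1),
                 "no activity")
  expect_true(all(vapply(p0$counts, sum, numeric(1)) == 0))
  p1 <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 2000, seed = 5)
  p2 <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 2000, seed = 5)
  expect_identical(p1$counts, p2$counts)   # fixed seed, bit-identical
  p3 <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 2000, seed = 6)
  expect_false(identical(p1$counts$tc140, p3$counts$tc140))
  # Poisson sampling yields integers around the expectation
  pp <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 2000,
                             seed = 5, poisson = TRUE)
  expect_true(all(pp$counts$tc140 == round(pp$counts$tc140)))
  expect_equal(sum(pp$counts$tc140), sum(p1$counts$tc140), tolerance = 0.05)
})

test_that("counts scale linearly with acquisition time and activity", {
  s <- small_mc_setup()
  p1 <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 3000, seed = 5)
  geom2 <- s$geom; geom2$time_per_angle_s <- 2 * s$geom$time_per_angle_s
  p2 <- simulate_projections(s$ph, geom2, s$tabs, n_histories = 3000, seed = 5)
  expect_equal(sum(p2$counts$tc140) / sum(p1$counts$tc140), 2,
               tolerance = 1e-9)
  ph2 <- s$ph; ph2$activity_tc <- 2 * s$ph$activity_tc
  p3 <- simulate_projections(ph2, s$geom, s$tabs, n_histories = 3000, seed = 5)
  expect_equal(sum(p3$counts$tc140) / sum(p1$counts$tc140), 2,
               tolerance = 1e-9)
})

test_that("a pure 140-keV source without scatter or x-ray channels leaves the 81-keV window empty", {
  ph <- tiny_phantom(16, 16, voxel = 9.6, material = "air")
  ph$activity_tc[8, 8, 8] <- 1
  geom <- acquisition_geometry(n_angles = 4, nu = 16, nv = 16, pitch_mm = 9.6)
  # disable the collimator channels that can feed 81 keV from 140-keV photons
  tabs <- lapply(geom$windows, function(w)
    generate_psf_table(w, col = collimator_params(xray_amplitude = 0),
                       pitch_mm = 9.6, max_half = 12))
  # zero out residual penetration response for the Tc bin into the 81 window
  for (ie in seq_along(tabs$ho81$energies)) {
    for (id in seq_along(tabs$ho81$distances_mm)) {
      tabs$ho81$indirect[[ie]][[id]][] <- 0
    }
  }
  p <- simulate_projections(ph, geom, tabs, n_histories = 5000, seed = 2)
  # residual counts stem only from the vanishingly rare scatter in air
  expect_lt(sum(p$counts$ho81), 1e-3 * sum(p$counts$tc140))
  expect_gt(sum(p$counts$tc140), 0)
})

test_that("downscatter estimate is linear and broader than the photopeak", {
  s <- small_mc_setup()
  zero <- simulate_downscatter(0 * s$ph$activity_tc, s$ph, s$geom, s$tabs,
                               n_histories = 1000, seed = 3)
  expect_true(all(zero$counts == 0))
  d1 <- simulate_downscatter(s$ph$activity_tc, s$ph, s$geom, s$tabs,
                             n_histories = 8000, seed = 3)
  d2 <- simulate_downscatter(2 * s$ph$activity_tc, s$ph, s$geom, s$tabs,
                             n_histories = 8000, seed = 3)
  expect_equal(sum(d2$counts) / sum(d1$counts), 2, tolerance = 1e-9)
  # spatial second moment of the downscatter exceeds the photopeak's
  p <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 8000, seed = 3)
  m2 <- function(img) {
    w <- img / sum(img)
    u <- rowSums(w); v <- colSums(w)
    mu_u <- sum(u * seq_along(u)); mu_v <- sum(v * seq_along(v))
    sum(u * (seq_along(u) - mu_u)^2) + sum(v * (seq_along(v) - mu_v)^2)
  }
  expect_gt(m2(d1$counts[, , 1]), m2(p$counts$tc140[, , 1]))
})

test_that("window count ratios behave under superposition and scatter removal", {
  s <- small_mc_setup()
  p <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 8000, seed = 4)
  expect_equal(window_count_ratio(p, "tc140", "tc140"), 1)
  expect_error(window_count_ratio(p, "nope", "tc140"), "present")
  # vacuum transport (no scatter medium) strictly decreases C81/C140
  ph_air <- s$ph; ph_air$materials[] <- 0L
  p_air <- simulate_projections(ph_air, s$geom, s$tabs, n_histories = 8000,
                                seed = 4)
  expect_lt(window_count_ratio(p_air, "ho81", "tc140"),
            window_count_ratio(p, "ho81", "tc140"))
  # superposition: Ho-only + Tc-only expectations sum to the dual expectation
  ph_d <- s$ph; ph_d$activity_ho[6, 6, 8] <- 0.5
  ph_ho <- ph_d; ph_ho$activity_tc[] <- 0
  p_d <- simulate_projections(ph_d, s$geom, s$tabs, n_histories = 6000, seed = 8)
  p_ho <- simulate_projections(ph_ho, s$geom, s$tabs, n_histories = 6000, seed = 8)
  p_tc <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 6000, seed = 8)
  for (w in names(p_d$counts)) {
    expect_equal(sum(p_ho$counts[[w]]) + sum(p_tc$counts[[w]]),
                 sum(p_d$counts[[w]]), tolerance = 0.15)
  }
})

test_that("detected counts respect the conservation bound", {
  s <- small_mc_setup()
  p <- simulate_projections(s$ph, s$geom, s$tabs, n_histories = 5000, seed = 9)
  # emitted photons represented by the batch
  total_mbq <- phantom_total_activity(s$ph, "Tc99m")
  emitted <- total_mbq * 1e6 * s$geom$time_per_angle_s * 0.885
  max_eff <- max(vapply(s$tabs$tc140$direct, sum, numeric(1)))
  # per angle, detected photopeak counts cannot exceed emitted x best-case
  # efficiency (loose bound; scatter channels only remove counts)
  expect_lt(max(apply(p$counts$tc140, 3, sum)), emitted * max_eff * 4 * pi)
})
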
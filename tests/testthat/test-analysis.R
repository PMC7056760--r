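# analytic truth image of the NEMA spheres on a coarse grid
truth_image <- function(voxel = 2.4, n = c(96, 96, 48), conc = 0.8) {
  co <- duospect:::grid_coords(n, rep(voxel, 3))
  img <- array(0, n)
  lay <- nema_sphere_layout()
  for (i in seq_len(nrow(lay))) {
    img[duospect:::sphere_mask(co, c(lay$x[i], lay$y[i], 0),
                               lay$diameter_mm[i])] <- conc
  }
  img
}

gaussian_blur3 <- function(img, sigma_vox) {
  g <- dnorm(seq(-ceiling(3 * sigma_vox), ceiling(3 * sigma_vox)), 0, sigma_vox)
  g <- g / sum(g)
  for (d in 1:3) {
    img <- apply(img, setdiff(1:3, d), function(v)
      convolve(v, rev(g), type = "open")[
        (length(g) - 1) / 2 + seq_along(v)])
    img <- aperm(img, order(c(d, setdiff(1:3, d))))
  }
  img
}

test_that("VOI position fit recovers known shifts to sub-voxel accuracy", {
  img <- truth_image()
  fit0 <- fit_voi_positions(img, rep(2.4, 3))
  expect_lt(max(abs(fit0$offset)), 2.4)      # unshifted: within one voxel
  # shift the layout and refit: the recovered shift (relative to the
  # unshifted fit, which carries the voxelization bias of the discrete
  # sphere boundary) is accurate to half a voxel
  spec <- voi_spec()
  shift <- c(4.8, -2.4, 0)
  spec$x <- spec$x - shift[1]; spec$y <- spec$y - shift[2]
  fit <- fit_voi_positions(img, rep(2.4, 3), spec = spec)
  expect_lt(max(abs((fit$offset - fit0$offset) - shift)), 1.2)
  # optimality: fit value at the recovered offset >= value at zero offset
  expect_gte(fit$value,
             duospect:::voi_fit_value(img, rep(2.4, 3), spec, c(0, 0, 0)))
  expect_error(fit_voi_positions(0 * img, rep(2.4, 3)), "all-zero")
})

test_that("recovery coefficients are exact on truth and monotone under blur", {
  img <- truth_image()
  rc <- recovery_coefficients(img, rep(2.4, 3), voi_spec(), true_conc = 0.8)
  expect_equal(rc$recovery_pct, rep(100, 6), tolerance = 1e-9)
  # wide blur: matched-VOI recovery strictly increases with sphere diameter
  blurred <- gaussian_blur3(img, sigma_vox = 4)
  rcb <- recovery_coefficients(blurred, rep(2.4, 3), voi_spec(),
                               true_conc = 0.8)
  expect_true(all(diff(rcb$recovery_pct) > 0))
  # dilated VOIs on truth recapture all activity up to voxelization error
  rcd <- recovery_coefficients(img, rep(2.4, 3), voi_spec(dilation_mm = 20),
                               true_conc = 0.8)
  expect_true(all(abs(rcd$recovery_pct - 100) < 8))
  # dilated recovery on the blurred image captures the spill-out
  rcbd <- recovery_coefficients(blurred, rep(2.4, 3),
                                voi_spec(dilation_mm = 20), true_conc = 0.8)
  expect_true(all(rcbd$recovery_pct >= rcb$recovery_pct))
})

test_that("dilation sweep is anchored at the matched VOIs and bounded at 40 mm", {
  img <- gaussian_blur3(truth_image(), 3)
  sw <- dilation_sweep(img, rep(2.4, 3), dilations_mm = c(0, 16, 32, 40))
  rc0 <- recovery_coefficients(img, rep(2.4, 3), voi_spec(), true_conc = 0.8)
  expect_equal(sw$recovery_pct[sw$dilation_mm == 0], rc0$recovery_pct)
  for (s in unique(sw$sphere)) {
    r <- sw$recovery_pct[sw$sphere == s]
    expect_true(all(diff(r) > -0.5))   # non-decreasing capture of spill-out
  }
  expect_error(dilation_sweep(img, rep(2.4, 3), dilations_mm = c(0, 44)),
               "overlap")
  expect_error(duospect:::check_dilation(41), "overlap")
  expect_silent(duospect:::check_dilation(40))
})

test_that("line profiles sum, average and normalize as specified", {
  counts <- list(
    ho81 = array(1, c(8, 6, 4)),
    sc118 = array(2, c(8, 6, 4)),
    tc140 = array(1:8, c(8, 6, 4)),
    sc170 = array(0.5, c(8, 6, 4)))
  geom <- acquisition_geometry(n_angles = 4, nu = 8, nv = 6, pitch_mm = 4.8)
  proj <- duospect:::new_projection_set(counts, geom)
  prof <- line_profile(proj, mode = "sum")
  expect_true(all(prof$ho81 == 6))                 # flat for all-ones input
  expect_equal(prof$tc140, (1:8) * 6)
  norm <- line_profile(proj, mode = "sum", normalize = "tc140")
  expect_equal(sum(norm$tc140), 1, tolerance = 1e-12)
  # the same scale factor is applied to every window
  expect_equal(norm$ho81 / prof$ho81, rep(1 / sum(prof$tc140), 8),
               tolerance = 1e-12)
  avg <- line_profile(proj, mode = "average_angles",
                      box = list(u = c(2, 7), v = c(1, 6)))
  expect_equal(avg$u, 2:7)
  expect_true(all(avg$ho81 == 6))
})

test_that("crosstalk ratio arithmetic reduces to the protocol's ratios", {
  r <- crosstalk_ratios(c(2, 4), c(5, 1))
  expect_equal(r$ratio81, c(5, 2))
  expect_equal(r$ratio140, c(5, 4))
  expect_equal(r$value81, 2.5)
  expect_equal(r$value140, 1.25)
  expect_equal(crosstalk_ratios(c(1, 1), c(1, 1))$ratio81, c(1, 1))
  r10 <- crosstalk_ratios(c(2, 4), c(10, 1))
  expect_equal(r10$ratio81, c(5, 1))
  expect_equal(r10$ratio140, c(5, 2))
  expect_error(crosstalk_ratios(c(0, 4), c(5, 1)))
})
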
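test_that("energy window bounds follow the center/width convention", {
  cases <- list(list(81, 0.15, c(74.925, 87.075)),
                list(140, 0.15, c(129.5, 150.5)),
                list(170, 0.12, c(159.8, 180.2)),
                list(118, 0.12, c(110.92, 125.08)))
  for (cs in cases) {
    b <- window_bounds(cs[[1]], cs[[2]])
    expect_equal(unname(b), cs[[3]], tolerance = 1e-12)
    expect_lt(b[1], cs[[1]])
    expect_gt(b[2], cs[[1]])
  }
  expect_error(window_bounds(-10, 0.15), "positive")
  expect_error(window_bounds(140, 1.2), "width_fraction")
})

test_that("detection probability is the Gaussian mass inside the window", {
  det <- detector_model(fwhm_ref = 0.095, e_ref = 140, exponent = 0.5)
  w <- energy_window("tc140", 140, 0.15)
  # photon at the window center with a narrow resolution: essentially 1
  det_narrow <- detector_model(fwhm_ref = 0.005)
  expect_gt(detection_probability(140, w, det_narrow), 0.999)
  # photon exactly at a bound of a window much wider than the FWHM: 1/2
  expect_equal(detection_probability(w$lo, w, det_narrow), 0.5,
               tolerance = 1e-3)
  # photon 3 FWHM below the lower bound: numeric Gaussian-integral oracle
  fw <- energy_fwhm(det, w$lo - 3 * energy_fwhm(det, w$lo))
  e_far <- w$lo - 3 * fw
  sigma <- energy_fwhm(det, e_far) / (2 * sqrt(2 * log(2)))
  oracle <- integrate(function(x) dnorm(x, e_far, sigma), w$lo, w$hi)$value
  got <- detection_probability(e_far, w, det)
  expect_lt(got, 0.01)
  expect_equal(got, oracle, tolerance = 1e-6)
  # monotone in photon energy on each side of the window center
  below <- detection_probability(seq(100, 140, by = 2), w, det)
  above <- detection_probability(seq(140, 180, by = 2), w, det)
  expect_true(all(diff(below) > 0))
  expect_true(all(diff(above) < 0))
})

test_that("Compton kinematics and Klein-Nishina sampling are consistent", {
  # closed-form kinematic anchors at 140 keV
  expect_equal(compton_energy(140, pi), 140 / (1 + 2 * 140 / 510.999),
               tolerance = 1e-12)
  expect_equal(compton_energy(140, pi), 90.445, tolerance = 1e-4)
  expect_equal(compton_energy(140, pi / 2), 140 / (1 + 140 / 510.999),
               tolerance = 1e-12)
  expect_equal(compton_energy(140, pi / 2), 109.89, tolerance = 1e-3)

  set.seed(7)
  s <- sample_compton(140, 1e5)
  # kinematic bounds never violated, energy/angle mutually consistent
  expect_true(all(s$energy >= compton_energy(140, pi) - 1e-9))
  expect_true(all(s$energy <= 140 + 1e-9))
  expect_equal(s$energy, compton_energy(140, s$angle), tolerance = 1e-9)

  # KS distance against the numerically integrated Klein-Nishina CDF < 0.01
  kn_pdf_e <- function(ep, e0 = 140) {
    # dsigma/dE' via dsigma/dOmega * dOmega/dE'
    cost <- 1 - (e0 / ep - 1) * 510.999 / e0
    jac <- 2 * pi * 510.999 / ep^2                      # |dOmega/dE'|
    kn_differential(e0, acos(pmin(pmax(cost, -1), 1))) * jac
  }
  grid <- seq(compton_energy(140, pi), 140, length.out = 2001)
  pdf <- kn_pdf_e(grid)
  cdf <- cumsum(pdf) / sum(pdf)
  emp <- ecdf(s$energy)(grid)
  expect_lt(max(abs(emp - cdf)), 0.01)
})

test_that("attenuation lookup reproduces the packaged table and is monotone", {
  tab <- duospect_constants("attenuation")
  grid <- tab$energy_keV
  for (m in c("water", "pmma")) {
    mu_knots <- attenuation_coefficient(m, grid)
    expected <- tab$materials[[m]]$mu_over_rho_cm2_g *
      tab$materials[[m]]$density_g_cm3
    expect_equal(mu_knots, expected, tolerance = 1e-12)
    # interpolated values bounded by bracketing knots, monotone decreasing
    e_mid <- (head(grid, -1) + tail(grid, -1)) / 2
    mu_mid <- attenuation_coefficient(m, e_mid)
    expect_true(all(mu_mid <= pmax(head(mu_knots, -1), tail(mu_knots, -1))))
    expect_true(all(mu_mid >= pmin(head(mu_knots, -1), tail(mu_knots, -1))))
    expect_true(all(diff(attenuation_coefficient(m, seq(60, 2000, by = 20))) < 0))
  }
  expect_gt(attenuation_coefficient("water", 100),
            attenuation_coefficient("water", 140))
  expect_error(attenuation_coefficient("lead", 140), "unknown material")
  expect_error(attenuation_coefficient("water", 30), "range")
})

test_that("emission sampling reproduces the configured line intensities", {
  sp <- emission_spectrum("Ho166")
  set.seed(11)
  n <- 1e6
  e <- sample_emission_energy(sp, n)
  for (i in seq_len(nrow(sp$lines))) {
    p <- sp$lines$intensity[i] / sp$total_yield
    hits <- sum(abs(e - sp$lines$energy[i]) < 0.25)
    expect_lt(abs(hits - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
  # continuum samples spread over their bins
  cont <- e[e > 200 & e < 460]
  expect_gt(length(cont), 0)
  sp_tc <- emission_spectrum("Tc99m")
  expect_equal(sp_tc$total_yield, 0.885, tolerance = 1e-12)
  expect_true(all(sample_emission_energy(sp_tc, 100) == 140.5))
})
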
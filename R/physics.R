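# Photon physics: energy windows, emission spectra, detector energy response,
# attenuation lookup, and Klein-Nishina Compton sampling.

ELECTRON_REST_KEV <- 510.999

#' Define an acquisition energy window
#'
#' Windows are specified the way they are set on a gamma camera: a center
#' energy and a fractional width. Bounds follow `center * (1 +/- width/2)`.
#'
#' @param label Short window name (e.g. `"ho81"`, `"tc140"`).
#' @param center Window center in keV.
#' @param width_fraction Full fractional width (0.15 means a 15% window).
#' @return An object of class `energy_window` with fields `label`, `center`,
#'   `width_fraction`, `lo`, `hi` (keV).
#' @examples
#' energy_window("tc140", 140, 0.15)
#' @export
energy_window <- function(label, center, width_fraction) {
  b <- window_bounds(center, width_fraction)
  structure(list(label = label, center = center,
                 width_fraction = width_fraction,
                 lo = b[[1]], hi = b[[2]]),
            class = "energy_window")
}

#' @export
print.energy_window <- function(x, ...) {
  cat(sprintf("<energy_window %s: %.1f keV, %.0f%% [%.2f, %.2f] keV>\n",
              x$label, x$center, 100 * x$width_fraction, x$lo, x$hi))
  invisible(x)
}

#' Energy window bounds
#'
#' @param center Window center, keV (> 0).
#' @param width_fraction Fractional width in (0, 1).
#' @return Numeric vector `c(lo, hi)` in keV.
#' @examples
#' window_bounds(140, 0.15) # 129.5, 150.5
#' @export
window_bounds <- function(center, width_fraction) {
  if (!is.numeric(center) || length(center) != 1 || !is.finite(center) ||
      center <= 0) {
    stop("window center must be a positive number (keV)")
  }
  if (!is.numeric(width_fraction) || length(width_fraction) != 1 ||
      width_fraction <= 0 || width_fraction >= 1) {
    stop("width_fraction must lie in (0, 1)")
  }
  c(lo = center * (1 - width_fraction / 2),
    hi = center * (1 + width_fraction / 2))
}

#' The four clinically recorded windows of the dual-isotope protocol
#'
#' Photopeak windows for Ho-166 (81 keV, 15%) and Tc-99m (140 keV, 15%) plus
#' the two scatter windows at 118 and 170 keV (12% each).
#'
#' @return Named list of [energy_window()] objects: `ho81`, `sc118`, `tc140`,
#'   `sc170`.
#' @export
default_windows <- function() {
  list(ho81  = energy_window("ho81", 81, 0.15),
       sc118 = energy_window("sc118", 118, 0.12),
       tc140 = energy_window("tc140", 140, 0.15),
       sc170 = energy_window("sc170", 170, 0.12))
}

#' Isotope emission spectrum
#'
#' Loads the packaged spectrum for an isotope: discrete gamma lines plus, for
#' Ho-166, a coarse piecewise-constant bremsstrahlung continuum
#' (photons/decay per energy band). The continuum can be switched off to
#' study its contribution separately.
#'
#' @param isotope `"Ho166"` or `"Tc99m"`.
#' @param continuum Include the bremsstrahlung continuum (default `TRUE`;
#'   ignored for isotopes that have none).
#' @param lines Optional subset of line energies (keV) to keep, e.g.
#'   `lines = 80.57` restricts Ho-166 to its photopeak emission.
#' @return Object of class `emission_spectrum` with `isotope`, `lines`
#'   (data.frame `energy`, `intensity`), `continuum` (NULL or list with
#'   `edges`, `intensity` per bin), and `total_yield` photons/decay.
#' @export
emission_spectrum <- function(isotope = c("Ho166", "Tc99m"), continuum = TRUE,
                              lines = NULL) {
  isotope <- match.arg(isotope)
  cst <- duospect_constants("spectra")[[isotope]]
  ln <- data.frame(energy = as.numeric(cst$lines$energy_keV),
                   intensity = as.numeric(cst$lines$photons_per_decay))
  if (!is.null(lines)) {
    keep <- vapply(ln$energy, function(e) any(abs(e - lines) < 0.5), logical(1))
    ln <- ln[keep, , drop = FALSE]
  }
  cont <- NULL
  if (continuum && !is.null(cst$continuum) && length(cst$continuum)) {
    cont <- list(edges = as.numeric(cst$continuum$edges_keV),
                 intensity = as.numeric(cst$continuum$photons_per_decay))
  }
  structure(list(isotope = isotope, lines = ln, continuum = cont,
                 total_yield = sum(ln$intensity) +
                   if (is.null(cont)) 0 else sum(cont$intensity)),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum %s: %d lines, %s continuum, %.4f photons/decay>\n",
              x$isotope, nrow(x$lines),
              if (is.null(x$continuum)) "no" else "with", x$total_yield))
  invisible(x)
}

# Flatten a spectrum into sampling bins: each row has (e_lo, e_hi, prob).
# Discrete lines have e_lo == e_hi; continuum bins sample uniformly in energy.
spectrum_bins <- function(spectrum) {
  lo <- spectrum$lines$energy
  hi <- spectrum$lines$energy
  p <- spectrum$lines$intensity
  if (!is.null(spectrum$continuum)) {
    ed <- spectrum$continuum$edges
    lo <- c(lo, head(ed, -1))
    hi <- c(hi, tail(ed, -1))
    p <- c(p, spectrum$continuum$intensity)
  }
  list(e_lo = lo, e_hi = hi, prob = p / sum(p), yield = sum(p))
}

#' Sample emission energies from a spectrum
#'
#' @param spectrum An [emission_spectrum()].
#' @param n Number of photons.
#' @return Numeric vector of energies in keV.
#' @export
sample_emission_energy <- function(spectrum, n) {
  b <- spectrum_bins(spectrum)
  i <- sample.int(length(b$prob), n, replace = TRUE, prob = b$prob)
  b$e_lo[i] + runif(n) * (b$e_hi[i] - b$e_lo[i])
}

#' Gamma camera energy-resolution model
#'
#' FWHM as a fraction of energy scales as `fwhm_ref * (e_ref / E)^exponent`,
#' the usual statistical-broadening law for NaI(Tl) when `exponent = 0.5`.
#'
#' @param fwhm_ref Fractional FWHM at the reference energy (default 0.095,
#'   i.e. 9.5% at 140 keV, a typical NaI value).
#' @param e_ref Reference energy, keV.
#' @param exponent Resolution exponent (>= 0).
#' @return Object of class `detector_model`.
#' @export
detector_model <- function(fwhm_ref = 0.095, e_ref = 140, exponent = 0.5) {
  stopifnot(fwhm_ref > 0, e_ref > 0, exponent >= 0)
  structure(list(fwhm_ref = fwhm_ref, e_ref = e_ref, exponent = exponent),
            class = "detector_model")
}

#' Absolute energy resolution FWHM at a photon energy
#'
#' @param det A [detector_model()].
#' @param energy Photon energy, keV (vectorized).
#' @return FWHM in keV.
#' @export
energy_fwhm <- function(det, energy) {
  det$fwhm_ref * (det$e_ref / energy)^det$exponent * energy
}

#' Probability of detecting a photon inside an energy window
#'
#' The recorded energy is modeled as Gaussian around the true photon energy
#' with the camera's energy-dependent FWHM; the detection probability is the
#' Gaussian mass falling inside the window bounds.
#'
#' @param photon_energy Photon energy, keV (vectorized).
#' @param window An [energy_window()].
#' @param det A [detector_model()].
#' @return Probability in `[0, 1]` per photon.
#' @export
detection_probability <- function(photon_energy, window, det = detector_model()) {
  if (any(photon_energy <= 0)) stop("photon_energy must be positive")
  sigma <- energy_fwhm(det, photon_energy) / (2 * sqrt(2 * log(2)))
  pnorm((window$hi - photon_energy) / sigma) -
    pnorm((window$lo - photon_energy) / sigma)
}

# ---- attenuation ------------------------------------------------------------

ATTENUATION_E_RANGE <- c(60, 2000)

attenuation_table <- function() {
  if (is.null(.duospect_env$att_table)) {
    .duospect_env$att_table <- duospect_constants("attenuation")
  }
  .duospect_env$att_table
}

#' Patient materials known to the attenuation model
#' @return Character vector of material names.
#' @export
attenuation_materials <- function() names(attenuation_table()$materials)

loglog_interp <- function(xg, yg, x) {
  exp(approx(log(xg), log(yg), xout = log(x), rule = 1)$y)
}

#' Linear attenuation coefficient of a patient material
#'
#' Looks up the packaged mass attenuation table (log-log interpolated between
#' grid energies) and multiplies by the material density.
#'
#' @param material One of [attenuation_materials()] (water, pmma, bone, air,
#'   agar).
#' @param energy Photon energy in keV, within 60-2000 (vectorized).
#' @return mu in 1/cm.
#' @examples
#' attenuation_coefficient("water", 140)
#' @export
attenuation_coefficient <- function(material, energy) {
  tab <- attenuation_table()$materials[[material]]
  if (is.null(tab)) stop("unknown material: ", material)
  if (any(energy < ATTENUATION_E_RANGE[1] | energy > ATTENUATION_E_RANGE[2])) {
    stop("energy outside the tabulated 60-2000 keV range")
  }
  grid <- attenuation_table()$energy_keV
  loglog_interp(grid, tab$mu_over_rho_cm2_g, energy) * tab$density_g_cm3
}

#' Linear attenuation coefficient of lead (collimator model)
#'
#' Lead is tabulated separately (it has a K-edge at 88 keV and is used only
#' by the collimator PSF generator, not as a patient material).
#'
#' @param energy keV, vectorized; clamped to the tabulated 60-2000 keV range.
#' @return mu in 1/cm.
#' @export
lead_attenuation <- function(energy) {
  tab <- attenuation_table()$collimator_materials$lead
  e <- pmin(pmax(energy, min(tab$energy_keV)), max(tab$energy_keV))
  loglog_interp(tab$energy_keV, tab$mu_over_rho_cm2_g, e) * tab$density_g_cm3
}

# Compton (incoherent) linear attenuation from the Klein-Nishina total
# cross-section and the material's electron density; used to split total
# interactions into Compton vs photoelectric inside the transport core.
compton_attenuation <- function(material, energy) {
  tab <- attenuation_table()$materials[[material]]
  if (is.null(tab)) stop("unknown material: ", material)
  # electron density per cm^3 recovered from the packaged table at high energy,
  # where the photoelectric term is negligible.
  grid <- attenuation_table()$energy_keV
  ne <- tab$mu_over_rho_cm2_g[length(grid)] / kn_total_cross_section(grid[length(grid)])
  ne * kn_total_cross_section(energy) * tab$density_g_cm3
}

#' Klein-Nishina total cross-section per electron
#'
#' @param energy Photon energy in keV (vectorized).
#' @return Cross-section in cm^2 per electron.
#' @export
kn_total_cross_section <- function(energy) {
  k <- energy / ELECTRON_REST_KEV
  r_e2 <- 7.940787e-26
  t1 <- (1 + k) / k^3 * (2 * k * (1 + k) / (1 + 2 * k) - log(1 + 2 * k))
  t2 <- log(1 + 2 * k) / (2 * k)
  t3 <- (1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * r_e2 * (t1 + t2 - t3)
}

#' Klein-Nishina differential cross-section
#'
#' `d sigma / d Omega` at scattering angle `theta` for incident energy
#' `energy`, per electron.
#'
#' @param energy Incident photon energy, keV.
#' @param theta Scattering polar angle, radians (vectorized).
#' @return cm^2 / sr per electron.
#' @export
kn_differential <- function(energy, theta) {
  k <- energy / ELECTRON_REST_KEV
  eps <- 1 / (1 + k * (1 - cos(theta)))
  r_e2 <- 7.940787e-26
  r_e2 / 2 * eps^2 * (eps + 1 / eps - sin(theta)^2)
}

#' Compton-scattered energy at a given angle
#'
#' @param energy Incident energy, keV.
#' @param theta Scattering angle, radians (vectorized).
#' @return Scattered photon energy, keV.
#' @export
compton_energy <- function(energy, theta) {
  energy / (1 + energy / ELECTRON_REST_KEV * (1 - cos(theta)))
}

#' Sample Compton scattering from the Klein-Nishina distribution
#'
#' Kahn's composition-rejection method. Returns the scattered energy and the
#' polar scattering angle for each sample; the two are kinematically
#' consistent (`scattered = E / (1 + E/m_e c^2 (1 - cos theta))`).
#'
#' @param energy Incident photon energy, keV (scalar).
#' @param n Number of samples.
#' @return data.frame with columns `energy` (keV) and `angle` (radians).
#' @export
sample_compton <- function(energy, n) {
  stopifnot(energy > 0, n >= 1)
  s <- mc_sample_compton(energy, as.integer(n))
  data.frame(energy = s$energy, angle = s$angle)
}
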
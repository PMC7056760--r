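# Energy- and distance-indexed point-spread-function lookup tables.
#
# The collimator/detector response is a parameterized analytic model standing
# in for full radiation-transport simulation of the camera head: a Gaussian
# geometric core for photons accepted by the holes, a broad exponential
# septal-penetration tail whose amplitude grows with energy, and a narrow
# near-field component representing lead K x-rays (72-88 keV) generated in the
# collimator, which feed the 81-keV window.

#' Photon-energy to PSF-source-energy bin map
#'
#' The eight tabulated PSF source energies and the half-open energy bands
#' (lower edge inclusive) that select them.
#'
#' @return List with `edges` (9 band edges, keV) and `energies` (8 PSF source
#'   energies, keV).
#' @export
psf_energy_bins <- function() {
  list(edges = c(60, 88, 106, 129, 154, 226, 462, 992, 2000),
       energies = c(81, 95, 118, 140, 170, 300, 713, 1379))
}

#' Map a photon energy to its associated PSF source energy
#'
#' Bins are half-open `[lo, hi)` with the lower edge inclusive; the top edge
#' (2000 keV) is included in the last bin.
#'
#' @param photon_energy keV, within 60-2000 (vectorized).
#' @return PSF source energy in keV (one of 81, 95, 118, 140, 170, 300, 713,
#'   1379).
#' @examples
#' psf_energy_bin(100) # 95
#' @export
psf_energy_bin <- function(photon_energy) {
  b <- psf_energy_bins()
  if (any(photon_energy < b$edges[1] | photon_energy > b$edges[length(b$edges)])) {
    stop("photon energy outside the 60-2000 keV PSF range")
  }
  idx <- findInterval(photon_energy, b$edges, rightmost.closed = TRUE)
  b$energies[idx]
}

#' Collimator parameters (medium-energy parallel-hole defaults)
#'
#' @param hole_diameter_mm Hole diameter.
#' @param hole_length_mm Hole (septal) length.
#' @param septal_thickness_mm Septal thickness.
#' @param hole_shape_factor Geometric-efficiency shape constant (0.26 for
#'   hexagonal holes).
#' @param intrinsic_fwhm_mm Intrinsic detector resolution added in quadrature.
#' @param crystal_thickness_mm NaI crystal thickness.
#' @param detector_area_mm2 Active camera area (bounds the solid angle of the
#'   uncollimated penetration/x-ray channels).
#' @param xray_amplitude Lead K x-ray channel amplitude: the product of
#'   fluorescence yield, septal escape probability, in-window fraction and
#'   angular acceptance, folded into one tunable constant.
#' @param pen_tail_scale Penetration tail decay length as a fraction of the
#'   source-collimator distance.
#' @param multi_deposit_factor Down-weighting of window deposits that require
#'   more than one crystal interaction.
#' @param highe_deposit_factor Boost of the penetration-channel efficiency
#'   for source energies of 226 keV and above, standing in for
#'   collimator-scatter cascades and the low-energy weighting of the crystal
#'   deposit spectrum that the minimal analytic terms miss.
#' @param highe_xray_factor Corresponding boost of the lead x-ray channel
#'   for source energies of 226 keV and above (MeV photons cascade in the
#'   collimator and shielding, producing more K x-rays than the bare
#'   photoelectric fraction suggests).
#' @return List of class `collimator_params`.
#' @export
collimator_params <- function(hole_diameter_mm = 2.94,
                              hole_length_mm = 40.64,
                              septal_thickness_mm = 1.14,
                              hole_shape_factor = 0.26,
                              intrinsic_fwhm_mm = 3.8,
                              crystal_thickness_mm = 9.5,
                              detector_area_mm2 = 400 * 500,
                              xray_amplitude = 3e-4,
                              pen_tail_scale = 0.4,
                              multi_deposit_factor = 0.3,
                              highe_deposit_factor = 2,
                              highe_xray_factor = 24) {
  stopifnot(hole_diameter_mm > 0, hole_length_mm > 0, septal_thickness_mm > 0)
  structure(as.list(environment()), class = "collimator_params")
}

# NaI linear attenuation, coarse parameterization (1/cm)
nai_attenuation <- function(energy) {
  e <- c(60, 80, 100, 140, 170, 200, 300, 500, 800, 1000, 1400, 1700, 2000)
  mu_rho <- c(4.0, 2.0, 1.68, 0.70, 0.43, 0.33, 0.17, 0.095, 0.065,
              0.058, 0.049, 0.046, 0.044)
  loglog_interp(e, mu_rho, pmin(pmax(energy, 60), 2000)) * 3.67
}

# Minimum septal crossing path (mm): s*l / (2d + s)
septal_path_mm <- function(col) {
  with(col, septal_thickness_mm * hole_length_mm /
         (2 * hole_diameter_mm + septal_thickness_mm))
}

# Geometric collimator efficiency per isotropically emitted photon
geometric_efficiency <- function(col, energy) {
  l_eff <- collimator_l_eff_mm(col, energy)
  with(col, (hole_shape_factor * hole_diameter_mm / l_eff)^2 *
         (hole_diameter_mm / (hole_diameter_mm + septal_thickness_mm))^2)
}

collimator_l_eff_mm <- function(col, energy) {
  mu <- lead_attenuation(energy) / 10  # 1/mm
  max(col$hole_length_mm - 2 / mu, 1)
}

# Geometric resolution FWHM (mm) at source-collimator distance d (mm)
geometric_fwhm_mm <- function(col, distance_mm, energy) {
  l_eff <- collimator_l_eff_mm(col, energy)
  col$hole_diameter_mm * (l_eff + distance_mm) / l_eff
}

# radial kernel builders on a (2h+1)^2 grid ---------------------------------
kernel_radius_grid <- function(half, pitch_mm) {
  ax <- (-half:half) * pitch_mm
  sqrt(outer(ax^2, ax^2, "+"))
}

gaussian_kernel <- function(half, pitch_mm, fwhm_mm, efficiency) {
  r <- kernel_radius_grid(half, pitch_mm)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  k <- exp(-r^2 / (2 * sigma^2))
  k / sum(k) * efficiency
}

exponential_kernel <- function(half, pitch_mm, scale_mm, efficiency) {
  r <- kernel_radius_grid(half, pitch_mm)
  k <- exp(-r / scale_mm)
  # normalize against the full (untruncated) analytic mass so that truncation
  # shows up as lost efficiency rather than being renormalized away
  full_mass <- 2 * pi * scale_mm^2 / pitch_mm^2
  k / full_mass * efficiency
}

truncate_kernel <- function(k, rel = 1e-6) {
  k[k < rel * max(k)] <- 0
  k
}

#' Build the PSF lookup table for one energy window
#'
#' Generates indirect kernels for the 8 tabulated PSF source energies at the
#' 5 tabulated source-collimator distances (1, 5, 12, 24, 40 cm), plus the
#' "direct" kernel family (photons whose energy lies inside the window) versus
#' distance. Kernels hold counts per emitted photon; their sums are the
#' channel efficiencies and are at most 1.
#'
#' @param window Target [energy_window()].
#' @param col [collimator_params()].
#' @param det [detector_model()].
#' @param pitch_mm Detector pixel pitch of the kernel grid.
#' @param max_half Kernel half-width in pixels (support is `2*max_half+1`
#'   square); tails below `trunc_rel` of the peak are zeroed and the lost
#'   mass is reported in the table's `truncation_loss`.
#' @param trunc_rel Relative truncation threshold.
#' @return Object of class `psf_table`.
#' @export
generate_psf_table <- function(window, col = collimator_params(),
                               det = detector_model(), pitch_mm = 4.8,
                               max_half = 24, trunc_rel = 1e-6) {
  bins <- psf_energy_bins()
  distances_mm <- c(10, 50, 120, 240, 400)
  sp_mm <- septal_path_mm(col)

  omega_frac <- function(d_mm) {
    pmin(0.5, col$detector_area_mm2 / (4 * pi * pmax(d_mm, 50)^2))
  }
  win_width <- window$hi - window$lo

  indirect <- vector("list", length(bins$energies))
  trunc_loss <- 0
  for (ie in seq_along(bins$energies)) {
    e <- bins$energies[ie]
    mu_pb <- lead_attenuation(e) / 10                       # 1/mm
    p_pen <- exp(-mu_pb * sp_mm)
    p_int <- 1 - exp(-nai_attenuation(e) / 10 * col$crystal_thickness_mm)
    edge <- e - compton_energy(e, pi)                        # Compton edge
    f_win <- min(0.5, win_width / e) *
      if (edge >= window$lo) 1 else col$multi_deposit_factor
    pe_frac <- 1 / (1 + (e / 600)^1.8)
    xray_on <- e > 88 && window$lo < 88 && window$hi > 72
    dl <- vector("list", length(distances_mm))
    for (id in seq_along(distances_mm)) {
      d <- distances_mm[id]
      eff_pen <- p_pen * p_int * f_win * omega_frac(d) *
        if (e >= 226) col$highe_deposit_factor else 1
      k <- exponential_kernel(max_half, pitch_mm,
                              max(10, col$pen_tail_scale * d), eff_pen)
      if (xray_on) {
        eff_x <- omega_frac(d) * (1 - p_pen) * pe_frac * 0.8 *
          col$xray_amplitude * if (e >= 226) col$highe_xray_factor else 1
        k <- k + gaussian_kernel(max_half, pitch_mm, 10 + 0.05 * d, eff_x)
      }
      full <- sum(k)
      k <- truncate_kernel(k, trunc_rel)
      trunc_loss <- trunc_loss + (full - sum(k))
      dl[[id]] <- k
    }
    indirect[[ie]] <- dl
  }

  direct <- vector("list", length(distances_mm))
  g <- geometric_efficiency(col, window$center)
  for (id in seq_along(distances_mm)) {
    d <- distances_mm[id]
    fwhm <- sqrt(geometric_fwhm_mm(col, d, window$center)^2 +
                   col$intrinsic_fwhm_mm^2)
    direct[[id]] <- truncate_kernel(
      gaussian_kernel(max_half, pitch_mm, fwhm, g), trunc_rel)
  }

  structure(list(energies = bins$energies, edges = bins$edges,
                 distances_mm = distances_mm, indirect = indirect,
                 direct = direct, pitch_mm = pitch_mm, max_half = max_half,
                 window = window, collimator = col, detector = det,
                 truncation_loss = trunc_loss),
            class = "psf_table")
}

#' @export
print.psf_table <- function(x, ...) {
  cat(sprintf(paste0("<psf_table window %s: %d energies x %d distances, ",
                     "%dx%d kernels, pitch %.2f mm>\n"),
              x$window$label, length(x$energies), length(x$distances_mm),
              2 * x$max_half + 1, 2 * x$max_half + 1, x$pitch_mm))
  invisible(x)
}

# linear blend of two kernels in distance
interp_kernel_list <- function(kl, distances_mm, distance_mm) {
  d <- distance_mm
  if (d < min(distances_mm) || d > max(distances_mm)) {
    warning("PSF distance ", d / 10, " cm clamped to the tabulated 1-40 cm range")
    d <- min(max(d, min(distances_mm)), max(distances_mm))
  }
  i <- findInterval(d, distances_mm, rightmost.closed = TRUE)
  i <- min(max(i, 1), length(distances_mm) - 1)
  t <- (d - distances_mm[i]) / (distances_mm[i + 1] - distances_mm[i])
  (1 - t) * kl[[i]] + t * kl[[i + 1]]
}

#' Look up (and distance-interpolate) a PSF kernel
#'
#' Returns the stored kernel exactly at tabulated distances and the
#' element-wise linear blend between the two bracketing distances otherwise.
#' Distances outside 1-40 cm are clamped with a warning.
#'
#' @param photon_energy keV (selects the indirect kernel via
#'   [psf_energy_bin()]; ignored when `direct = TRUE`).
#' @param distance_cm Source-collimator distance in cm.
#' @param table A [generate_psf_table()] result.
#' @param direct Return the direct (in-window) kernel; the caller weights it
#'   by [detection_probability()].
#' @return Matrix kernel; `sum(kernel)` is the channel efficiency.
#' @export
psf_for <- function(photon_energy, distance_cm, table, direct = FALSE) {
  d_mm <- distance_cm * 10
  if (direct) {
    return(interp_kernel_list(table$direct, table$distances_mm, d_mm))
  }
  e <- psf_energy_bin(photon_energy)
  ie <- match(e, table$energies)
  interp_kernel_list(table$indirect[[ie]], table$distances_mm, d_mm)
}

#' Write / read a PSF table as a MetaImage stack plus JSON index
#'
#' @param table A `psf_table`.
#' @param path Base path (without extension).
#' @return `write_psf_table` returns `path` invisibly; `read_psf_table`
#'   returns the `psf_table`.
#' @export
write_psf_table <- function(table, path) {
  n <- 2 * table$max_half + 1
  nd <- length(table$distances_mm)
  ne <- length(table$energies)
  stack <- array(0, dim = c(n, n, nd * (ne + 1)))
  s <- 1
  for (ie in seq_len(ne)) for (id in seq_len(nd)) {
    stack[, , s] <- table$indirect[[ie]][[id]]; s <- s + 1
  }
  for (id in seq_len(nd)) { stack[, , s] <- table$direct[[id]]; s <- s + 1 }
  write_volume(stack, paste0(path, ".mhd"),
               spacing = c(table$pitch_mm, table$pitch_mm, 1),
               sidecar = list(kind = "psf_table",
                              energies = table$energies, edges = table$edges,
                              distances_mm = table$distances_mm,
                              pitch_mm = table$pitch_mm,
                              max_half = table$max_half,
                              window = unclass(table$window),
                              truncation_loss = table$truncation_loss))
  invisible(path)
}

#' @rdname write_psf_table
#' @export
read_psf_table <- function(path) {
  v <- read_volume(paste0(path, ".mhd"))
  sc <- v$sidecar
  nd <- length(sc$distances_mm)
  ne <- length(sc$energies)
  indirect <- vector("list", ne)
  s <- 1
  for (ie in seq_len(ne)) {
    dl <- vector("list", nd)
    for (id in seq_len(nd)) { dl[[id]] <- v$data[, , s]; s <- s + 1 }
    indirect[[ie]] <- dl
  }
  direct <- vector("list", nd)
  for (id in seq_len(nd)) { direct[[id]] <- v$data[, , s]; s <- s + 1 }
  w <- energy_window(sc$window$label, sc$window$center, sc$window$width_fraction)
  structure(list(energies = sc$energies, edges = sc$edges,
                 distances_mm = sc$distances_mm, indirect = indirect,
                 direct = direct, pitch_mm = sc$pitch_mm,
                 max_half = sc$max_half, window = w,
                 collimator = NULL, detector = NULL,
                 truncation_loss = sc$truncation_loss),
            class = "psf_table")
}
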
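# Monte Carlo projection simulator: photon histories through the voxel
# attenuation map (Woodcock tracking, Klein-Nishina scattering) scored into
# per-window projections via the energy/distance PSF lookup tables.

#' SPECT acquisition geometry
#'
#' @param n_angles Number of projection angles (default 120).
#' @param arc_deg Total rotation arc in degrees (default 360).
#' @param radius_cm Radius of rotation (collimator face to isocenter).
#' @param nu,nv Detector bins along the transaxial (u) and axial (v)
#'   directions.
#' @param pitch_mm Detector bin pitch (both directions).
#' @param windows Named list of [energy_window()] objects to record.
#' @param time_per_angle_s Acquisition time per angle, seconds.
#' @param sensitivity Global sensitivity scale (counts multiplier, default 1).
#' @return Object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(n_angles = 120, arc_deg = 360,
                                 radius_cm = 25, nu = 64, nv = 64,
                                 pitch_mm = 4.8, windows = default_windows(),
                                 time_per_angle_s = 10, sensitivity = 1) {
  stopifnot(n_angles >= 1, radius_cm > 0, nu >= 1, nv >= 1, pitch_mm > 0)
  angles <- (seq_len(n_angles) - 1) / n_angles * arc_deg * pi / 180
  structure(list(n_angles = n_angles, arc_deg = arc_deg, angles = angles,
                 radius_cm = radius_cm, nu = nu, nv = nv, pitch_mm = pitch_mm,
                 windows = windows, time_per_angle_s = time_per_angle_s,
                 sensitivity = sensitivity),
            class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("<acquisition_geometry: %d angles/%g deg, R=%g cm, %dx%d @ %g mm, windows: %s>\n",
              x$n_angles, x$arc_deg, x$radius_cm, x$nu, x$nv, x$pitch_mm,
              paste(names(x$windows), collapse = ", ")))
  invisible(x)
}

new_projection_set <- function(counts, geometry, seed = NA_integer_,
                               n_histories = NA_real_, poisson = FALSE) {
  structure(list(counts = counts, geometry = geometry, seed = seed,
                 n_histories = n_histories, poisson = poisson),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  tot <- vapply(x$counts, sum, numeric(1))
  cat("<projection_set:",
      paste(sprintf("%s=%.3g", names(tot), tot), collapse = ", "),
      if (x$poisson) "(Poisson sampled)>" else "(expectation)>", "\n")
  invisible(x)
}

mu_table_matrices <- function() {
  att <- attenuation_table()
  grid <- att$energy_keV
  mats <- MATERIAL_LEVELS
  mu_tot <- t(vapply(mats, function(m)
    att$materials[[m]]$mu_over_rho_cm2_g * att$materials[[m]]$density_g_cm3,
    numeric(length(grid))))
  mu_com <- t(vapply(mats, function(m)
    compton_attenuation(m, grid), numeric(length(grid))))
  list(e_grid = grid, mu_tot = mu_tot, mu_com = mu_com)
}

# sample emission positions (mm, volume-center origin) proportional to an
# activity map
sample_emission_positions <- function(activity, voxel_mm, n) {
  nz <- which(activity > 0)
  if (!length(nz)) return(NULL)
  pick <- nz[sample.int(length(nz), n, replace = TRUE,
                        prob = activity[nz])]
  d <- dim(activity)
  ix <- (pick - 1L) %% d[1]
  iy <- ((pick - 1L) %/% d[1]) %% d[2]
  iz <- (pick - 1L) %/% (d[1] * d[2])
  cbind((ix - (d[1] - 1) / 2 + runif(n) - 0.5) * voxel_mm[1],
        (iy - (d[2] - 1) / 2 + runif(n) - 0.5) * voxel_mm[2],
        (iz - (d[3] - 1) / 2 + runif(n) - 0.5) * voxel_mm[3])
}

# FFT-based 2-D "same" convolution with zero boundary.
conv2_same <- function(x, k) {
  nx <- nrow(x); ny <- ncol(x)
  hk <- (nrow(k) - 1) %/% 2
  px <- nx + 2 * hk; py <- ny + 2 * hk
  X <- matrix(0, px, py); X[seq_len(nx), seq_len(ny)] <- x
  K <- matrix(0, px, py); K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  f <- Re(fft(fft(X) * fft(K), inverse = TRUE)) / (px * py)
  f[hk + seq_len(nx), hk + seq_len(ny)]
}

# Core: transport + per-angle scoring for one isotope's activity map.
# Returns list of expectation count arrays [nu, nv, n_angles], one per window
# in geom$windows (restricted to `score_windows` if given).
mc_project <- function(activity, phantom, spectrum, psf_tables, geom,
                       n_histories, det = detector_model(),
                       score_windows = NULL,
                       skip_unscattered_direct = FALSE) {
  wins <- geom$windows
  if (!is.null(score_windows)) wins <- wins[score_windows]
  stopifnot(length(wins) >= 1, length(psf_tables) == length(wins))
  total_mbq <- sum(activity) * prod(phantom$voxel_mm) / 1000
  out <- lapply(wins, function(w)
    array(0, dim = c(geom$nu, geom$nv, geom$n_angles)))
  if (total_mbq <= 0 || n_histories <= 0) {
    warning("empty phantom: returning zero projections")
    return(out)
  }
  mt <- mu_table_matrices()
  pos0 <- sample_emission_positions(activity, phantom$voxel_mm, n_histories)
  e0 <- sample_emission_energy(spectrum, n_histories)
  events <- mc_transport(pos0, e0, phantom$materials, as.integer(phantom$dim),
                         phantom$voxel_mm, mt$e_grid, mt$mu_tot, mt$mu_com,
                         e_cutoff = 50, max_scatters = 10L, w_min = 1e-4)
  all_pos <- rbind(pos0, events$pos)
  all_e <- c(e0, events$energy)
  all_w <- c(rep(1, n_histories), events$weight)
  all_dir <- rbind(matrix(0, n_histories, 3), events$dir)
  all_type <- c(rep(0L, n_histories), rep(1L, nrow(events$pos)))

  bins <- psf_energy_bins()
  winmat <- t(vapply(wins, function(w) c(w$lo, w$hi), numeric(2)))
  dist_knots <- psf_tables[[1]]$distances_mm
  nk <- length(dist_knots)
  nbin <- length(bins$energies)
  # decays per angle represented by the batch (per emitted photon weight)
  scale <- total_mbq * 1e6 * geom$time_per_angle_s * spectrum$total_yield *
    geom$sensitivity / n_histories
  step_mm <- min(phantom$voxel_mm) / 2

  for (ia in seq_len(geom$n_angles)) {
    acc <- mc_score_angle(all_pos, all_e, all_w, all_dir, all_type,
                          geom$angles[ia], phantom$materials,
                          as.integer(phantom$dim), phantom$voxel_mm,
                          mt$e_grid, mt$mu_tot, mt$mu_com, winmat,
                          det$fwhm_ref, det$e_ref, det$exponent,
                          bins$edges, dist_knots,
                          geom$radius_cm * 10, geom$nu, geom$nv,
                          geom$pitch_mm, geom$pitch_mm, step_mm,
                          skip_unscattered_direct)
    dim(acc) <- c(geom$nu, geom$nv, nk, nbin + 1, length(wins))
    for (iw in seq_along(wins)) {
      tab <- psf_tables[[iw]]
      img <- matrix(0, geom$nu, geom$nv)
      for (ik in seq_len(nk)) {
        sl <- acc[, , ik, nbin + 1, iw]
        if (any(sl != 0)) img <- img + conv2_same(sl, tab$direct[[ik]])
        for (ib in seq_len(nbin)) {
          sl <- acc[, , ik, ib, iw]
          if (any(sl != 0))
            img <- img + conv2_same(sl, tab$indirect[[ib]][[ik]])
        }
      }
      out[[iw]][, , ia] <- img * scale
    }
  }
  out
}

#' Simulate per-window SPECT projections of a dual-isotope phantom
#'
#' Photon histories are sampled proportionally to the voxel activities of
#' both isotopes, emitted with energies from the packaged spectra,
#' transported through the material map (Compton scattering per
#' Klein-Nishina, photoelectric absorption), and scored toward every
#' projection angle by forced detection: direct (in-window) photons through
#' the distance-interpolated direct PSF weighted by the detection
#' probability, out-of-window photons through the indirect PSF selected by
#' [psf_energy_bin()]. Counts are scaled to total activity x time per angle.
#'
#' @param phantom A `voxel_phantom`.
#' @param geom An [acquisition_geometry()].
#' @param psf_tables Named list of [generate_psf_table()] results, one per
#'   window in `geom$windows` (built automatically when `NULL`).
#' @param n_histories Photon histories per isotope.
#' @param seed RNG seed (recorded in the result).
#' @param poisson Sample Poisson noise around the expectation.
#' @param det Energy-resolution [detector_model()].
#' @return A `projection_set` with one counts array `[nu, nv, n_angles]` per
#'   window.
#' @export
simulate_projections <- function(phantom, geom = acquisition_geometry(),
                                 psf_tables = NULL, n_histories = 1e5,
                                 seed = 1, poisson = FALSE,
                                 det = detector_model()) {
  set.seed(seed)
  if (is.null(psf_tables)) psf_tables <- psf_tables_for(geom, det)
  counts <- lapply(geom$windows, function(w)
    array(0, dim = c(geom$nu, geom$nv, geom$n_angles)))
  any_act <- FALSE
  for (iso in c("Tc99m", "Ho166")) {
    act <- if (iso == "Tc99m") phantom$activity_tc else phantom$activity_ho
    if (sum(act) <= 0) next
    any_act <- TRUE
    sp <- emission_spectrum(iso)
    part <- mc_project(act, phantom, sp, psf_tables, geom, n_histories,
                       det = det)
    for (w in names(counts)) counts[[w]] <- counts[[w]] + part[[w]]
  }
  if (!any_act) warning("phantom has no activity: zero projections")
  if (poisson) {
    counts <- lapply(counts, function(x)
      array(rpois(length(x), x), dim = dim(x)))
  }
  new_projection_set(counts, geom, seed = seed, n_histories = n_histories,
                     poisson = poisson)
}

#' Build the per-window PSF tables for a geometry
#'
#' @param geom An [acquisition_geometry()].
#' @param det A [detector_model()].
#' @param col [collimator_params()].
#' @param max_half Kernel half width in pixels.
#' @return Named list of `psf_table`, one per window.
#' @export
psf_tables_for <- function(geom, det = detector_model(),
                           col = collimator_params(), max_half = 24) {
  key <- paste0("psf_", paste(vapply(geom$windows, function(w) w$label,
                                     character(1)), collapse = "_"),
                "_", geom$pitch_mm, "_", max_half,
                "_", col$xray_amplitude, "_", det$fwhm_ref)
  if (is.null(.duospect_env[[key]])) {
    .duospect_env[[key]] <- lapply(geom$windows, function(w)
      generate_psf_table(w, col = col, det = det, pitch_mm = geom$pitch_mm,
                         max_half = max_half))
  }
  .duospect_env[[key]]
}

#' Monte Carlo estimate of Tc-99m downscatter in the 81-keV window
#'
#' Simulates the Tc-99m activity image (typically the step-1 reconstruction)
#' and scores only the Ho-166 photopeak window, excluding nothing: every
#' detected Tc count in that window is crosstalk. The estimate is the
#' noise-free expectation and is linear in the input image.
#'
#' @param tc_image Tc-99m activity array (MBq/ml) on the phantom grid, or an
#'   `activity_image`.
#' @param phantom `voxel_phantom` providing grid and materials.
#' @param geom [acquisition_geometry()] (must contain window `ho81`).
#' @param psf_tables Per-window PSF tables (as in [simulate_projections()]).
#' @param n_histories Photon histories.
#' @param seed RNG seed.
#' @param target_window Window label to score (default `"ho81"`).
#' @param det [detector_model()].
#' @return A `scatter_estimate`: list with `window`, `counts`
#'   `[nu, nv, n_angles]`.
#' @export
simulate_downscatter <- function(tc_image, phantom,
                                 geom = acquisition_geometry(),
                                 psf_tables = NULL, n_histories = 1e5,
                                 seed = 1, target_window = "ho81",
                                 det = detector_model()) {
  if (inherits(tc_image, "activity_image")) tc_image <- tc_image$data
  stopifnot(all(tc_image >= 0))
  set.seed(seed)
  if (is.null(psf_tables)) psf_tables <- psf_tables_for(geom, det)
  zero <- array(0, dim = c(geom$nu, geom$nv, geom$n_angles))
  if (sum(tc_image) <= 0) {
    return(scatter_estimate(target_window, zero))
  }
  sp <- emission_spectrum("Tc99m")
  part <- mc_project(tc_image, phantom, sp, psf_tables[target_window], geom,
                     n_histories, det = det, score_windows = target_window)
  scatter_estimate(target_window, part[[target_window]])
}

#' Construct a scatter estimate
#'
#' Expected (noise-free) additive counts in one window, used inside OSEM.
#'
#' @param window Window label.
#' @param counts Array `[nu, nv, n_angles]`, nonnegative.
#' @return Object of class `scatter_estimate`.
#' @export
scatter_estimate <- function(window, counts) {
  stopifnot(all(counts >= 0))
  structure(list(window = window, counts = counts), class = "scatter_estimate")
}

#' Total-count ratio between two windows
#'
#' @param proj A `projection_set`.
#' @param wA,wB Window labels (e.g. `"ho81"`, `"tc140"`).
#' @return `sum(counts[wA]) / sum(counts[wB])`.
#' @export
window_count_ratio <- function(proj, wA, wB) {
  if (!all(c(wA, wB) %in% names(proj$counts))) {
    stop("both windows must be present in the projection set")
  }
  sum(proj$counts[[wA]]) / sum(proj$counts[[wB]])
}
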
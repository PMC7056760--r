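# Quantitative evaluation: VOI auto-placement, recovery coefficients,
# dilation sweeps, convergence curves, line profiles, and crosstalk-ratio
# arithmetic.

#' VOI specification for the NEMA spheres
#'
#' @param layout Sphere layout as from [nema_sphere_layout()] (needs
#'   `diameter_mm`, `x`, `y`; sphere plane at z = 0).
#' @param dilation_mm Increase of every VOI diameter, mm (0: matched VOIs;
#'   20 is the protocol's dilated setting).
#' @return data.frame with one row per VOI: `sphere`, `diameter_mm`,
#'   `voi_diameter_mm`, centers `x`, `y`, `z`.
#' @export
voi_spec <- function(layout = nema_sphere_layout(), dilation_mm = 0) {
  stopifnot(dilation_mm >= 0)
  data.frame(sphere = seq_len(nrow(layout)),
             diameter_mm = layout$diameter_mm,
             voi_diameter_mm = layout$diameter_mm + dilation_mm,
             x = layout$x, y = layout$y, z = 0)
}

# Guard against VOIs grown past the validated non-overlap bound: beyond a
# 40-mm diameter increase dilated VOIs start to reach into neighboring
# spheres on the NEMA ring.
MAX_DILATION_MM <- 40

check_dilation <- function(dilation_mm, spec = NULL) {
  if (any(dilation_mm > MAX_DILATION_MM)) {
    stop("VOI dilation beyond +", MAX_DILATION_MM,
         " mm: VOIs overlap neighboring spheres")
  }
  if (!is.null(spec)) {
    # geometric VOI-vs-sphere overlap check on the actual layout
    n <- nrow(spec)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dist <- sqrt((spec$x[i] - spec$x[j])^2 + (spec$y[i] - spec$y[j])^2 +
                     (spec$z[i] - spec$z[j])^2)
      if (spec$voi_diameter_mm[i] / 2 + spec$diameter_mm[j] / 2 > dist) {
        stop(sprintf("VOI %d (diameter %.0f mm) overlaps sphere %d",
                     i, spec$voi_diameter_mm[i], j))
      }
    }
  }
  invisible(TRUE)
}

# trilinear interpolation of a volume at mm coordinates (center origin)
interp_volume <- function(vol, voxel_mm, pts) {
  n <- dim(vol)
  gx <- pts[, 1] / voxel_mm[1] + (n[1] + 1) / 2
  gy <- pts[, 2] / voxel_mm[2] + (n[2] + 1) / 2
  gz <- pts[, 3] / voxel_mm[3] + (n[3] + 1) / 2
  x0 <- pmin(pmax(floor(gx), 1), n[1] - 1)
  y0 <- pmin(pmax(floor(gy), 1), n[2] - 1)
  z0 <- pmin(pmax(floor(gz), 1), n[3] - 1)
  fx <- pmin(pmax(gx - x0, 0), 1)
  fy <- pmin(pmax(gy - y0, 0), 1)
  fz <- pmin(pmax(gz - z0, 0), 1)
  at <- function(i, j, k) vol[cbind(i, j, k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x0 + 1, y0, z0)) +
              fy * ((1 - fx) * at(x0, y0 + 1, z0) + fx * at(x0 + 1, y0 + 1, z0))) +
    fz * ((1 - fy) * ((1 - fx) * at(x0, y0, z0 + 1) + fx * at(x0 + 1, y0, z0 + 1)) +
          fy * ((1 - fx) * at(x0, y0 + 1, z0 + 1) + fx * at(x0 + 1, y0 + 1, z0 + 1)))
}

# unit-sphere sample points for VOI means (deterministic spiral lattice)
voi_sample_points <- function(n_pts = 200) {
  i <- seq_len(n_pts) - 0.5
  phi <- acos(1 - 2 * i / n_pts)
  theta <- pi * (1 + sqrt(5)) * i
  r <- (i / n_pts)^(1 / 3)
  cbind(r * sin(phi) * cos(theta), r * sin(phi) * sin(theta), r * cos(phi))
}

# mean image value over all VOIs at a rigid offset (sub-voxel, trilinear)
voi_fit_value <- function(image, voxel_mm, spec, offset) {
  pts <- voi_sample_points()
  tot <- 0
  for (i in seq_len(nrow(spec))) {
    c0 <- c(spec$x[i], spec$y[i], spec$z[i]) + offset
    p <- sweep(pts * spec$voi_diameter_mm[i] / 2, 2, c0, "+")
    tot <- tot + mean(interp_volume(image, voxel_mm, p))
  }
  tot
}

#' Fit the VOI layout position on an image
#'
#' Finds the rigid offset of the known sphere layout that maximizes the
#' summed mean VOI activity: a coarse exhaustive search on a sub-voxel grid
#' followed by local refinement. Ties break deterministically toward the
#' smallest offset in lexicographic order.
#'
#' @param image Activity array or `activity_image`.
#' @param voxel_mm Voxel size (taken from the image when it is an
#'   `activity_image`).
#' @param spec [voi_spec()] layout.
#' @param search_mm Half-range of the coarse search (per axis).
#' @param step_mm Coarse search step.
#' @return List with `offset` (mm, length 3) and `value` (fit objective).
#' @export
fit_voi_positions <- function(image, voxel_mm = NULL,
                              spec = voi_spec(), search_mm = 6,
                              step_mm = 2) {
  if (inherits(image, "activity_image")) {
    voxel_mm <- image$voxel_mm
    image <- image$data
  }
  if (sum(image) <= 0) stop("cannot fit VOI positions on an all-zero image")
  g <- seq(-search_mm, search_mm, by = step_mm)
  cand <- as.matrix(expand.grid(x = g, y = g, z = g))
  ord <- order(abs(cand[, 1]) + abs(cand[, 2]) + abs(cand[, 3]),
               cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  vals <- apply(cand, 1, function(o) voi_fit_value(image, voxel_mm, spec, o))
  best <- cand[which.max(vals), ]          # first max wins -> smallest offset
  ref <- optim(best, function(o) -voi_fit_value(image, voxel_mm, spec, o),
               method = "Nelder-Mead",
               control = list(maxit = 100, reltol = 1e-6))
  off <- ref$par
  val <- -ref$value
  if (val < max(vals)) { off <- best; val <- max(vals) }
  list(offset = unname(off), value = val)
}

#' Recovery coefficients per sphere
#'
#' Matched VOIs (`dilation_mm = 0`) report the mean VOI concentration as a
#' percentage of the true concentration; dilated VOIs report the total VOI
#' activity as a percentage of the true sphere activity (the spill-out
#' captured by the enlarged VOI).
#'
#' @param image Calibrated activity array (MBq/ml) or `activity_image`.
#' @param voxel_mm Voxel size, mm (from the `activity_image` if given).
#' @param spec [voi_spec()]; its `voi_diameter_mm` fixes the metric
#'   (matched vs dilated).
#' @param true_conc True sphere concentration, MBq/ml.
#' @param offset Rigid layout offset from [fit_voi_positions()].
#' @return data.frame per sphere: `sphere`, `diameter_mm`,
#'   `voi_diameter_mm`, `mean_conc`, `recovery_pct` (rounded to 0.1%).
#' @export
recovery_coefficients <- function(image, voxel_mm = NULL, spec = voi_spec(),
                                  true_conc = 0.8, offset = c(0, 0, 0)) {
  if (inherits(image, "activity_image")) {
    voxel_mm <- image$voxel_mm
    image <- image$data
  }
  check_dilation(spec$voi_diameter_mm - spec$diameter_mm, spec)
  n <- dim(image)
  co <- grid_coords(n, voxel_mm)
  vox_ml <- prod(voxel_mm) / 1000
  out <- spec[, c("sphere", "diameter_mm", "voi_diameter_mm")]
  out$mean_conc <- NA_real_
  out$recovery_pct <- NA_real_
  for (i in seq_len(nrow(spec))) {
    ctr <- c(spec$x[i], spec$y[i], spec$z[i]) + offset
    m <- sphere_mask(co, ctr, spec$voi_diameter_mm[i])
    vals <- image[m]
    if (!length(vals)) {
      # VOI smaller than the voxel grid can miss every voxel center;
      # fall back to a trilinear sample at the VOI center
      vals <- interp_volume(image, voxel_mm, matrix(ctr, 1))
    }
    out$mean_conc[i] <- mean(vals)
    dilated <- spec$voi_diameter_mm[i] > spec$diameter_mm[i] + 1e-9
    rc <- if (dilated) {
      true_act <- true_conc * 4 / 3 * pi * (spec$diameter_mm[i] / 20)^3
      sum(vals) * vox_ml / true_act * 100
    } else {
      mean(vals) / true_conc * 100
    }
    out$recovery_pct[i] <- round(rc, 1)
  }
  out
}

#' Recovery coefficients versus iteration number
#'
#' @param snapshots List of per-iteration images (from `osem` with
#'   `save_iterations = TRUE`).
#' @param voxel_mm Voxel size, mm.
#' @param spec [voi_spec()].
#' @param true_conc True sphere concentration, MBq/ml.
#' @param offset VOI layout offset.
#' @param calibration Scale applied to each snapshot before analysis.
#' @return data.frame: `iteration`, `sphere`, `diameter_mm`, `recovery_pct`.
#' @export
convergence_curve <- function(snapshots, voxel_mm, spec = voi_spec(),
                              true_conc = 0.8, offset = c(0, 0, 0),
                              calibration = 1) {
  rows <- lapply(seq_along(snapshots), function(it) {
    rc <- recovery_coefficients(snapshots[[it]] * calibration, voxel_mm,
                                spec, true_conc, offset)
    cbind(iteration = it, rc[, c("sphere", "diameter_mm", "recovery_pct")])
  })
  do.call(rbind, rows)
}

#' Recovery versus VOI dilation
#'
#' @param image Activity array or `activity_image`.
#' @param voxel_mm Voxel size, mm.
#' @param dilations_mm Grid of VOI diameter increases (0-40 mm; beyond 40
#'   the VOIs overlap neighboring spheres and an error is raised).
#' @param layout Sphere layout.
#' @param true_conc True sphere concentration, MBq/ml.
#' @param offset VOI layout offset.
#' @return data.frame: `dilation_mm`, `sphere`, `diameter_mm`,
#'   `recovery_pct`.
#' @export
dilation_sweep <- function(image, voxel_mm = NULL,
                           dilations_mm = seq(0, 40, by = 8),
                           layout = nema_sphere_layout(), true_conc = 0.8,
                           offset = c(0, 0, 0)) {
  check_dilation(dilations_mm)
  rows <- lapply(dilations_mm, function(dd) {
    rc <- recovery_coefficients(image, voxel_mm, voi_spec(layout, dd),
                                true_conc, offset)
    cbind(dilation_mm = dd, rc[, c("sphere", "diameter_mm", "recovery_pct")])
  })
  do.call(rbind, rows)
}

#' Line profile through a projection stack
#'
#' @param proj A `projection_set`.
#' @param box List with `u` and `v` index ranges (each `c(from, to)`);
#'   defaults to the full detector.
#' @param mode `"sum"`: sum the first angle's image over `v` inside the box
#'   (profile along u, as for a line source); `"average_angles"`: average
#'   the stack over all angles first (as for the cylinder).
#' @param normalize Window label: scale every window's profile by the same
#'   factor that makes this window's summed intensity 1 (`NULL`: raw
#'   counts).
#' @return data.frame: `u`, one column per window.
#' @export
line_profile <- function(proj, box = NULL,
                         mode = c("sum", "average_angles"),
                         normalize = NULL) {
  mode <- match.arg(mode)
  g <- proj$geometry
  if (is.null(box)) box <- list(u = c(1, g$nu), v = c(1, g$nv))
  us <- box$u[1]:box$u[2]; vs <- box$v[1]:box$v[2]
  prof <- lapply(proj$counts, function(x) {
    img <- if (mode == "sum") x[, , 1] else apply(x, c(1, 2), mean)
    rowSums(img[us, vs, drop = FALSE])
  })
  if (!is.null(normalize)) {
    sc <- sum(prof[[normalize]])
    if (sc > 0) prof <- lapply(prof, function(p) p / sc)
  }
  cbind(data.frame(u = us), as.data.frame(prof))
}

#' Crosstalk count ratios at an administered activity ratio
#'
#' Given the per-activity crosstalk factors (Tc counts per unit activity
#' relative to Ho counts per unit activity) in the two photopeak windows,
#' returns the Ho:Tc count ratios at an administered Ho:Tc activity ratio,
#' reduced to lowest terms when integral.
#'
#' @param per_activity_factors `c(f81, f140)`: Tc-to-Ho counts-per-activity
#'   factors in the 81- and 140-keV windows (the protocol's values are about
#'   2 and 4).
#' @param activity_ratio `c(ho, tc)` administered activities (the protocol
#'   uses 5:1).
#' @return List with `ratio81` and `ratio140`, each `c(ho, tc)` reduced to
#'   lowest integer terms when possible, plus `value81`, `value140`
#'   (numeric Ho/Tc count ratios).
#' @export
crosstalk_ratios <- function(per_activity_factors = c(2, 4),
                             activity_ratio = c(5, 1)) {
  stopifnot(all(per_activity_factors > 0), all(activity_ratio > 0))
  reduce <- function(a, b) {
    if (abs(a - round(a)) < 1e-9 && abs(b - round(b)) < 1e-9) {
      a <- round(a); b <- round(b)
      g <- function(x, y) if (y == 0) x else g(y, x %% y)
      d <- g(a, b)
      c(a / d, b / d)
    } else c(a, b)
  }
  r81 <- reduce(activity_ratio[1], activity_ratio[2] * per_activity_factors[1])
  r140 <- reduce(activity_ratio[1], activity_ratio[2] * per_activity_factors[2])
  list(ratio81 = r81, ratio140 = r140,
       value81 = r81[1] / r81[2], value140 = r140[1] / r140[2])
}

#' Plot recovery-vs-iteration convergence curves
#'
#' @param curve Output of [convergence_curve()].
#' @param main Plot title.
#' @return Invisibly, the input.
#' @export
plot_convergence <- function(curve, main = "Activity recovery vs iteration") {
  spheres <- sort(unique(curve$sphere))
  cols <- grDevices::hcl.colors(length(spheres), "Dark 3")
  graphics::plot(range(curve$iteration), range(curve$recovery_pct),
                 type = "n", xlab = "OSEM iteration", ylab = "recovery (%)",
                 main = main)
  for (i in seq_along(spheres)) {
    s <- curve[curve$sphere == spheres[i], ]
    graphics::lines(s$iteration, s$recovery_pct, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright",
                   legend = paste0(curve$diameter_mm[match(spheres, curve$sphere)],
                                   " mm"),
                   col = cols, lwd = 2, bty = "n")
  invisible(curve)
}
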
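# Rotation-based attenuated forward/back projector with distance-dependent
# PSF: the deterministic in-window (primary-photon) system model used inside
# OSEM. Parallel-beam geometry; the volume is rotated per angle with a sparse
# bilinear-interpolation operator, attenuated along the exit path at the
# window's center energy, and convolved per depth group with the
# distance-interpolated direct PSF kernel. The back projector is the exact
# adjoint (transposed rotation, identical symmetric kernels).

# sparse bilinear rotation operator: rotated[u, t] = image at lab coords
# (-u sin a + t cos a, u cos a + t sin a); u, t centered voxel units.
rotation_operator <- function(n, angle) {
  half <- (n + 1) / 2
  u <- rep(seq_len(n) - half, times = n)
  t <- rep(seq_len(n) - half, each = n)
  xs <- -u * sin(angle) + t * cos(angle) + half
  ys <- u * cos(angle) + t * sin(angle) + half
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  row <- rep(seq_len(n * n), 4)
  cx <- c(x0, x0 + 1, x0, x0 + 1)
  cy <- c(y0, y0, y0 + 1, y0 + 1)
  wgt <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  ok <- cx >= 1 & cx <= n & cy >= 1 & cy <= n & wgt > 0
  Matrix::sparseMatrix(i = row[ok], j = (cy[ok] - 1L) * n + cx[ok],
                       x = wgt[ok], dims = c(n * n, n * n))
}

# cached-FFT "same" convolution pair for a fixed image size
make_conv <- function(nx, nz, kernel) {
  hk <- (nrow(kernel) - 1) %/% 2
  px <- nx + 2 * hk; pz <- nz + 2 * hk
  K <- matrix(0, px, pz)
  K[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  Kf <- fft(K)
  function(x) {
    X <- matrix(0, px, pz)
    X[seq_len(nx), seq_len(nz)] <- x
    f <- Re(fft(fft(X) * Kf, inverse = TRUE)) / (px * pz)
    f[hk + seq_len(nx), hk + seq_len(nz)]
  }
}

#' Build the OSEM system model for one isotope window
#'
#' @param phantom `voxel_phantom` on the reconstruction grid (provides the
#'   material map); alternatively pass `mu_map` directly.
#' @param geom [acquisition_geometry()]; `nu`/`nv`/`pitch_mm` must match the
#'   phantom grid (`nx`/`nz`/voxel).
#' @param window The isotope's photopeak [energy_window()]; attenuation is
#'   evaluated at its center energy.
#' @param psf_table `psf_table` for the window (the direct kernel family is
#'   used); built automatically when `NULL`.
#' @param yield Photons per decay feeding the window (photopeak line
#'   intensity); taken from the packaged spectrum via `isotope` when `NULL`.
#' @param isotope `"Ho166"` or `"Tc99m"`, used to look up `yield`.
#' @param mu_map Optional attenuation map (1/cm) overriding the phantom
#'   materials.
#' @param n_depth_groups Depth planes are pooled into this many groups, each
#'   sharing one distance-interpolated PSF kernel.
#' @param det [detector_model()]: the photopeak line's energy-window
#'   detection probability is folded into the count scale so the projector
#'   matches the Monte Carlo simulator's absolute scale.
#' @param scatter_amplitude In-patient scatter modeled inside the system
#'   matrix: each depth kernel gains a broad component carrying
#'   `scatter_amplitude` times the direct kernel's efficiency. The dual
#'   pipeline calibrates this amplitude per study with its Monte Carlo
#'   self-scatter estimate; 0 gives the pure primary-photon model.
#' @param scatter_scale_mm Decay length of the broad scatter component.
#' @return Object of class `system_model` with cached rotation operators and
#'   kernel FFTs.
#' @export
system_model <- function(phantom, geom, window, psf_table = NULL,
                         yield = NULL, isotope = NULL, mu_map = NULL,
                         n_depth_groups = 8, det = detector_model(),
                         scatter_amplitude = 0, scatter_scale_mm = 60) {
  n <- phantom$dim
  if (n[1] != n[2]) stop("projector requires nx == ny")
  if (geom$nu != n[1] || geom$nv != n[3] ||
      abs(geom$pitch_mm - phantom$voxel_mm[1]) > 1e-9) {
    stop("grid mismatch: detector bins/pitch must match the phantom grid")
  }
  if (is.null(psf_table)) {
    psf_table <- generate_psf_table(window, pitch_mm = geom$pitch_mm)
  }
  line_energy <- window$center
  if (is.null(yield)) {
    if (is.null(isotope)) stop("give either yield or isotope")
    sp <- emission_spectrum(isotope, continuum = FALSE)
    i <- which.min(abs(sp$lines$energy - window$center))
    yield <- sp$lines$intensity[i]
    line_energy <- sp$lines$energy[i]
  }
  yield <- yield * detection_probability(line_energy, window, det)
  if (is.null(mu_map)) {
    mu <- array(0, dim = n)
    for (m in seq_along(phantom$material_levels)) {
      sel <- phantom$materials == (m - 1L)
      if (any(sel)) {
        mu[sel] <- attenuation_coefficient(phantom$material_levels[m],
                                           window$center)
      }
    }
    mu_map <- mu
  }
  rot <- lapply(geom$angles, function(a) rotation_operator(n[1], a))
  rot_t <- lapply(rot, Matrix::t)

  # depth groups: contiguous blocks of depth planes sharing one kernel
  g <- sort(rep_len(seq_len(n_depth_groups), n[2]))
  groups <- split(seq_len(n[2]), g)
  half <- (n[2] + 1) / 2
  kernels <- lapply(groups, function(idx) {
    t_mm <- (mean(idx) - half) * phantom$voxel_mm[2]
    d_mm <- geom$radius_cm * 10 - t_mm
    k <- interp_kernel_list(psf_table$direct, psf_table$distances_mm,
                            min(max(d_mm, min(psf_table$distances_mm)),
                                max(psf_table$distances_mm)))
    if (scatter_amplitude > 0) {
      ks <- exp(-kernel_radius_grid(psf_table$max_half, psf_table$pitch_mm) /
                  scatter_scale_mm)
      k <- k + ks / sum(ks) * scatter_amplitude * sum(k)
    }
    k
  })
  convs <- lapply(kernels, function(k) make_conv(n[1], n[3], k))

  count_scale <- prod(phantom$voxel_mm) / 1000 * 1e6 *
    geom$time_per_angle_s * yield * geom$sensitivity
  structure(list(dim = n, voxel_mm = phantom$voxel_mm, geom = geom,
                 window = window, mu_map = mu_map, yield = yield,
                 rot = rot, rot_t = rot_t, groups = groups,
                 kernels = kernels, convs = convs,
                 count_scale = count_scale,
                 cache = new.env(parent = emptyenv())),
            class = "system_model")
}

#' @export
print.system_model <- function(x, ...) {
  cat(sprintf("<system_model %s: %s grid, %d angles, %d depth groups>\n",
              x$window$label, paste(x$dim, collapse = "x"),
              x$geom$n_angles, length(x$groups)))
  invisible(x)
}

# attenuation factor volume in the rotated frame (detector toward +t);
# cached per angle while the total cache stays below ~300 MB
rotated_attenuation <- function(model, ia) {
  key <- paste0("att", ia)
  cached <- model$cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- model$dim
  murot <- as.matrix(model$rot[[ia]] %*%
                       matrix(model$mu_map, n[1] * n[2], n[3]))
  dim(murot) <- n
  dy_cm <- model$voxel_mm[2] / 10
  # revcumsum along depth minus half the voxel's own mu
  s <- apply(murot[, n[2]:1, , drop = FALSE], c(1, 3), cumsum)
  # s is [t(rev), u, z]; reorder back to [u, t, z]
  s <- aperm(s[n[2]:1, , , drop = FALSE], c(2, 1, 3))
  att <- exp(-dy_cm * (s - 0.5 * murot))
  if (prod(n) * model$geom$n_angles * 8 < 3e8) model$cache[[key]] <- att
  att
}

#' Forward projection
#'
#' Expected in-window primary-photon counts for an activity image.
#'
#' @param image Activity array (MBq/ml) matching the model grid, or an
#'   `activity_image`.
#' @param model A [system_model()].
#' @param angles Optional subset of angle indices (used for OSEM subsets).
#' @return Array `[nu, nv, n_angles_used]` of expected counts.
#' @export
forward_project <- function(image, model, angles = NULL) {
  if (inherits(image, "activity_image")) image <- image$data
  if (!identical(dim(image), model$dim)) stop("grid mismatch")
  if (is.null(angles)) angles <- seq_len(model$geom$n_angles)
  n <- model$dim
  out <- array(0, dim = c(n[1], n[3], length(angles)))
  V <- matrix(image, n[1] * n[2], n[3])
  for (k in seq_along(angles)) {
    ia <- angles[k]
    rimg <- as.matrix(model$rot[[ia]] %*% V)
    dim(rimg) <- n
    w <- rimg * rotated_attenuation(model, ia)
    proj <- matrix(0, n[1], n[3])
    for (gi in seq_along(model$groups)) {
      sl <- w[, model$groups[[gi]], , drop = FALSE]
      s <- apply(sl, c(1, 3), sum)
      proj <- proj + model$convs[[gi]](s)
    }
    out[, , k] <- proj * model$count_scale
  }
  out
}

#' Back projection (exact adjoint of [forward_project()])
#'
#' @param projections Array `[nu, nv, n_angles_used]`.
#' @param model A [system_model()].
#' @param angles Optional subset of angle indices matching the projection
#'   stack's third dimension.
#' @return Image-domain array on the model grid.
#' @export
back_project <- function(projections, model, angles = NULL) {
  if (is.null(angles)) angles <- seq_len(model$geom$n_angles)
  n <- model$dim
  if (!identical(dim(projections), c(n[1], n[3], length(angles)))) {
    stop("grid mismatch")
  }
  acc <- matrix(0, n[1] * n[2], n[3])
  for (k in seq_along(angles)) {
    ia <- angles[k]
    att <- rotated_attenuation(model, ia)
    w <- array(0, dim = n)
    p <- projections[, , k] * model$count_scale
    for (gi in seq_along(model$groups)) {
      b <- model$convs[[gi]](p)
      w[, model$groups[[gi]], ] <-
        w[, model$groups[[gi]], , drop = FALSE] +
        aperm(array(b, dim = c(n[1], n[3], length(model$groups[[gi]]))),
              c(1, 3, 2))
    }
    w <- w * att
    acc <- acc + as.matrix(model$rot_t[[ia]] %*% matrix(w, n[1] * n[2], n[3]))
  }
  array(acc, dim = n)
}
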
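# Voxelized digital phantoms: per-isotope activity maps (MBq/ml) plus material
# labels on a common grid. All generators are deterministic given their
# arguments; sphere/cylinder membership uses the voxel-center-inside test.

MATERIAL_LEVELS <- c("air", "water", "pmma", "bone", "agar")

new_voxel_phantom <- function(activity_ho, activity_tc, materials, voxel_mm,
                              config) {
  stopifnot(identical(dim(activity_ho), dim(activity_tc)),
            identical(dim(activity_ho), dim(materials)))
  structure(list(dim = dim(activity_ho), voxel_mm = voxel_mm,
                 activity_ho = activity_ho, activity_tc = activity_tc,
                 materials = materials, material_levels = MATERIAL_LEVELS,
                 config = config),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  vol_ml <- prod(x$voxel_mm) / 1000
  cat(sprintf("<voxel_phantom %s: %s voxels @ %s mm, Ho %.2f MBq, Tc %.2f MBq>\n",
              x$config$name %||% "custom",
              paste(x$dim, collapse = "x"),
              paste(signif(x$voxel_mm, 3), collapse = "x"),
              sum(x$activity_ho) * vol_ml, sum(x$activity_tc) * vol_ml))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total activity of a phantom (MBq)
#'
#' @param phantom A `voxel_phantom`.
#' @param isotope `"Ho166"`, `"Tc99m"` or `"both"`.
#' @return Total activity in MBq.
#' @export
phantom_total_activity <- function(phantom, isotope = c("Ho166", "Tc99m", "both")) {
  isotope <- match.arg(isotope)
  vol_ml <- prod(phantom$voxel_mm) / 1000
  switch(isotope,
         Ho166 = sum(phantom$activity_ho) * vol_ml,
         Tc99m = sum(phantom$activity_tc) * vol_ml,
         both = (sum(phantom$activity_ho) + sum(phantom$activity_tc)) * vol_ml)
}

# voxel-center coordinate arrays (mm, origin at grid center)
grid_coords <- function(n, voxel_mm) {
  lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * voxel_mm[a])
}

# logical mask of voxel centers inside a sphere
sphere_mask <- function(coords, center, diameter_mm) {
  r2 <- (diameter_mm / 2)^2
  d2 <- outer(outer((coords[[1]] - center[1])^2,
                    (coords[[2]] - center[2])^2, "+"),
              (coords[[3]] - center[3])^2, "+")
  d2 <= r2
}

material_code <- function(name) match(name, MATERIAL_LEVELS) - 1L

#' NEMA IQ sphere layout
#'
#' The six fillable spheres (diameters 10-37 mm) on the standard 114.4-mm
#' pitch circle, ordered by size around the ring.
#'
#' @param ring_diameter_mm Pitch-circle diameter.
#' @return data.frame with `diameter_mm`, `volume_ml` (analytic), `x`, `y`
#'   center offsets (mm) in the sphere plane.
#' @export
nema_sphere_layout <- function(ring_diameter_mm = 114.4) {
  d <- c(10, 13, 17, 22, 28, 37)
  ang <- (seq_along(d) - 1) * pi / 3
  data.frame(diameter_mm = d,
             volume_ml = 4 / 3 * pi * (d / 20)^3,
             x = ring_diameter_mm / 2 * cos(ang),
             y = ring_diameter_mm / 2 * sin(ang))
}

#' NEMA image-quality phantom
#'
#' Six Ho-166 filled spheres on the standard ring inside a torso-shaped
#' (here: elliptic-cylinder) background compartment that carries the Tc-99m
#' background activity. Part of the compartment is filled with inert agar to
#' reduce the background volume to `background_volume_l` (default 5.5 L); a
#' central 50-mm air insert mimics the lung cylinder.
#'
#' @param tc_background Tc-99m background concentration, kBq/ml (0, 6, 11
#'   were the acquisition conditions; any value is accepted).
#' @param ho_spheres Ho-166 sphere concentration, MBq/ml (default 0.8).
#' @param voxel Isotropic voxel size, mm. Must resolve the 10-mm sphere
#'   (at least 3 voxels across); a warning is issued above 2 mm.
#' @param background_volume_l Background (Tc) compartment volume, litres.
#' @return A `voxel_phantom`.
#' @export
make_nema_iq <- function(tc_background = 0, ho_spheres = 0.8, voxel = 2,
                         background_volume_l = 5.5) {
  if (voxel > 10 / 3) stop("voxel too large to resolve the 10-mm sphere ",
                           "(need at least 3 voxels across)")
  if (voxel > 2) warning("voxel > 2 mm: sphere volume fidelity degrades")
  stopifnot(tc_background >= 0, ho_spheres >= 0, background_volume_l > 0)

  # interior: ellipse 280 x 210 mm, height 213 mm; central 50-mm air insert
  a <- 140; b <- 105; h <- 213; lung_d <- 50
  fov <- c(2 * a + 20, 2 * b + 20, h + 20)
  n <- as.integer(ceiling(fov / voxel))
  vx <- rep(voxel, 3)
  co <- grid_coords(n, vx)
  inside2d <- outer((co[[1]] / a)^2, (co[[2]] / b)^2, "+") <= 1
  lung2d <- outer(co[[1]]^2, co[[2]]^2, "+") <= (lung_d / 2)^2
  inz <- abs(co[[3]]) <= h / 2
  body <- outer(inside2d & !lung2d, inz, "&")
  lung <- outer(lung2d, inz, "&")

  materials <- array(material_code("air"), dim = n)
  materials[body] <- material_code("water")

  lay <- nema_sphere_layout()
  spheres <- array(FALSE, dim = n)
  for (i in seq_len(nrow(lay))) {
    m <- sphere_mask(co, c(lay$x[i], lay$y[i], 0), lay$diameter_mm[i])
    spheres <- spheres | m
  }

  # background = body minus spheres; fill with agar from one axial end (low z,
  # away from the sphere plane at z = 0) until the remaining (Tc) volume
  # matches the requested background volume
  bg <- body & !spheres
  vox_ml <- voxel^3 / 1000
  target_vox <- background_volume_l * 1000 / vox_ml
  counts_z <- apply(bg, 3, sum)
  cum_from_top <- rev(cumsum(rev(counts_z)))
  keep <- which(cum_from_top >= target_vox)
  cut_idx <- if (length(keep)) max(keep) else 1L
  agar_z <- seq_len(n[3]) < cut_idx
  agar <- bg & outer(array(TRUE, n[1:2]), agar_z, "&")
  materials[agar] <- material_code("agar")

  activity_ho <- array(0, dim = n)
  activity_ho[spheres] <- ho_spheres
  activity_tc <- array(0, dim = n)
  activity_tc[bg & !agar] <- tc_background / 1000   # kBq/ml -> MBq/ml

  new_voxel_phantom(activity_ho, activity_tc, materials, vx,
                    list(name = "nema_iq", tc_background_kbq_ml = tc_background,
                         ho_spheres_mbq_ml = ho_spheres, voxel_mm = voxel,
                         background_volume_l = background_volume_l,
                         sphere_layout = lay,
                         nominal_ho_mbq = ho_spheres * sum(lay$volume_ml)))
}

#' Homogeneous Tc-99m cylinder phantom
#'
#' @param volume_l Cylinder volume in litres (default 6.3).
#' @param tc_activity_mbq Total Tc-99m activity, MBq (default 50).
#' @param voxel Voxel size, mm.
#' @param diameter_mm Cylinder diameter (height follows from the volume).
#' @return A `voxel_phantom`; Tc concentration is `activity / volume`.
#' @export
make_cylinder <- function(volume_l = 6.3, tc_activity_mbq = 50, voxel = 2,
                          diameter_mm = 216) {
  stopifnot(volume_l > 0, tc_activity_mbq >= 0)
  r <- diameter_mm / 2
  height_mm <- volume_l * 1e6 / (pi * r^2)
  conc <- tc_activity_mbq / (volume_l * 1000)       # MBq/ml
  fov <- c(diameter_mm + 20, diameter_mm + 20, height_mm + 20)
  n <- as.integer(ceiling(fov / voxel))
  vx <- rep(voxel, 3)
  co <- grid_coords(n, vx)
  in2d <- outer(co[[1]]^2, co[[2]]^2, "+") <= r^2
  inz <- abs(co[[3]]) <= height_mm / 2
  cyl <- outer(in2d, inz, "&")
  materials <- array(material_code("air"), dim = n)
  materials[cyl] <- material_code("water")
  activity_tc <- array(0, dim = n)
  activity_tc[cyl] <- conc
  new_voxel_phantom(array(0, dim = n), activity_tc, materials, vx,
                    list(name = "cylinder", volume_l = volume_l,
                         tc_activity_mbq = tc_activity_mbq,
                         tc_conc_mbq_ml = conc, voxel_mm = voxel,
                         diameter_mm = diameter_mm, height_mm = height_mm))
}

#' Tc-99m line source between PMMA slabs
#'
#' A one-voxel-wide line of Tc-99m along the scanner axis, centered between
#' two 40 x 40 x 10 cm^3 slabs of PMMA scatter material; air elsewhere. The
#' slab material can be switched to water to study the effect of applying
#' water attenuation to a PMMA setup.
#'
#' @param line_activity_mbq Total line activity, MBq.
#' @param voxel Voxel size, mm.
#' @param slab_material `"pmma"` (default) or `"water"`.
#' @param line_length_mm Active line length.
#' @return A `voxel_phantom`.
#' @export
make_line_source_pmma <- function(line_activity_mbq = 50, voxel = 4,
                                  slab_material = c("pmma", "water"),
                                  line_length_mm = 300) {
  slab_material <- match.arg(slab_material)
  stopifnot(line_activity_mbq >= 0)
  # slabs: 400 (x) x 100 (y) x 400 (z) mm each, stacked along y around the line
  fov <- c(420, 2 * 100 + 3 * voxel + 20, 420)
  n <- as.integer(ceiling(fov / voxel))
  vx <- rep(voxel, 3)
  co <- grid_coords(n, vx)
  gap <- voxel * 1.5
  inx <- abs(co[[1]]) <= 200
  inz <- abs(co[[3]]) <= 200
  slab_y <- abs(co[[2]]) > gap / 2 & abs(co[[2]]) <= gap / 2 + 100
  slabs <- outer(outer(inx, slab_y, "&"), inz, "&")
  materials <- array(material_code("air"), dim = n)
  materials[slabs] <- material_code(slab_material)

  ix <- which.min(abs(co[[1]]))
  iy <- which.min(abs(co[[2]]))
  izs <- which(abs(co[[3]]) <= line_length_mm / 2)
  activity_tc <- array(0, dim = n)
  vox_ml <- prod(vx) / 1000
  activity_tc[ix, iy, izs] <- line_activity_mbq / (length(izs) * vox_ml)
  new_voxel_phantom(array(0, dim = n), activity_tc, materials, vx,
                    list(name = "line_source_pmma",
                         line_activity_mbq = line_activity_mbq,
                         slab_material = slab_material, voxel_mm = voxel,
                         line_length_mm = line_length_mm))
}

#' Anthropomorphic torso phantom with liver compartment and Ho insert
#'
#' Elliptic water body containing a spherical liver compartment carrying the
#' Tc-99m solution and, inside it, a spherical Ho-166 insert. Defaults follow
#' the 130-ml insert with 53 MBq Ho-166 (0.41 MBq/ml) inside a 1200-ml liver
#' at 34 kBq/ml Tc-99m.
#'
#' @param ho_insert `list(volume_ml=, activity_mbq=)` for the insert.
#' @param liver `list(volume_ml=, tc_conc_kbq_ml=)` for the liver compartment.
#' @param voxel Voxel size, mm.
#' @return A `voxel_phantom`.
#' @export
make_torso <- function(ho_insert = list(volume_ml = 130, activity_mbq = 53),
                       liver = list(volume_ml = 1200, tc_conc_kbq_ml = 34),
                       voxel = 2) {
  stopifnot(ho_insert$volume_ml > 0, liver$volume_ml > ho_insert$volume_ml)
  a <- 150; b <- 100; h <- 200
  fov <- c(2 * a + 20, 2 * b + 20, h + 20)
  n <- as.integer(ceiling(fov / voxel))
  vx <- rep(voxel, 3)
  co <- grid_coords(n, vx)
  body <- outer(outer((co[[1]] / a)^2, (co[[2]] / b)^2, "+") <= 1,
                abs(co[[3]]) <= h / 2, "&")
  r_liver <- (3 * liver$volume_ml * 1000 / (4 * pi))^(1 / 3)
  r_ins <- (3 * ho_insert$volume_ml * 1000 / (4 * pi))^(1 / 3)
  liver_center <- c(a / 2.5, 0, 0)
  liver_m <- sphere_mask(co, liver_center, 2 * r_liver)
  ins_m <- sphere_mask(co, liver_center + c(r_liver - r_ins - 5, 0, 0) * 0.5,
                       2 * r_ins)
  materials <- array(material_code("air"), dim = n)
  materials[body] <- material_code("water")
  activity_tc <- array(0, dim = n)
  activity_tc[liver_m & !ins_m] <- liver$tc_conc_kbq_ml / 1000
  activity_ho <- array(0, dim = n)
  activity_ho[ins_m] <- ho_insert$activity_mbq / ho_insert$volume_ml
  new_voxel_phantom(activity_ho, activity_tc, materials, vx,
                    list(name = "torso", ho_insert = ho_insert, liver = liver,
                         voxel_mm = voxel,
                         insert_conc_mbq_ml =
                           ho_insert$activity_mbq / ho_insert$volume_ml))
}

#' Resample a phantom to a coarser grid by volume-weighted averaging
#'
#' Activity concentrations are averaged (conserving total activity up to
#' edge effects); material labels take the majority vote.
#'
#' @param phantom A `voxel_phantom`.
#' @param voxel_out Target isotropic voxel size, mm (an integer multiple of
#'   the source voxel gives exact block averaging).
#' @param n_out Optional target grid size (length 3); defaults to covering
#'   the source extent.
#' @return A `voxel_phantom` on the target grid.
#' @export
resample_phantom <- function(phantom, voxel_out, n_out = NULL) {
  n_in <- phantom$dim
  vx_in <- phantom$voxel_mm
  if (is.null(n_out)) n_out <- as.integer(ceiling(n_in * vx_in / voxel_out))
  vx_out <- rep(voxel_out, 3)
  co_in <- grid_coords(n_in, vx_in)
  # map each fine voxel center to a coarse voxel index (center convention)
  idx <- lapply(1:3, function(a) {
    i <- round(co_in[[a]] / vx_out[a] + (n_out[a] + 1) / 2)
    as.integer(pmin(pmax(i, 1), n_out[a]))
  })
  lin <- as.integer(
    (rep(idx[[1]], times = n_in[2] * n_in[3]) - 1L) +
      n_out[1] * (rep(rep(idx[[2]], each = n_in[1]), times = n_in[3]) - 1L) +
      n_out[1] * n_out[2] * (rep(idx[[3]], each = n_in[1] * n_in[2]) - 1L)) + 1L
  nc <- prod(n_out)
  cnt <- tabulate(lin, nbins = nc)
  avg <- function(x) {
    s <- rowsum(as.vector(x), lin, reorder = FALSE)
    out <- numeric(nc)
    out[as.integer(rownames(s))] <- s[, 1]
    out / pmax(cnt, 1)
  }
  act_ho <- array(avg(phantom$activity_ho), dim = n_out)
  act_tc <- array(avg(phantom$activity_tc), dim = n_out)
  # majority material label
  mat <- array(material_code("air"), dim = n_out)
  best <- rep(-1L, nc)
  for (m in sort(unique(as.vector(phantom$materials)))) {
    cm <- tabulate(lin[as.vector(phantom$materials) == m], nbins = nc)
    upd <- cm > best
    mat[upd] <- m
    best[upd] <- cm[upd]
  }
  new_voxel_phantom(act_ho, act_tc, mat, vx_out,
                    modifyList(phantom$config,
                               list(resampled_from_mm = vx_in[1],
                                    voxel_mm = voxel_out)))
}
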
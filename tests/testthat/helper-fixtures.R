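# Shared fixtures: tiny grids and cached expensive objects. Everything is
# generated in code; nothing is read from disk.

# uniform water block phantom on an n x n x nz grid
tiny_phantom <- function(n = 8, nz = n, voxel = 4.8, material = "water") {
  dims <- c(n, n, nz)
  mat_code <- match(material, c("air", "water", "pmma", "bone", "agar")) - 1L
  structure(list(dim = as.integer(dims), voxel_mm = rep(voxel, 3),
                 activity_ho = array(0, dims), activity_tc = array(0, dims),
                 materials = array(mat_code, as.integer(dims)),
                 material_levels = c("air", "water", "pmma", "bone", "agar"),
                 config = list(name = "tiny")),
            class = "voxel_phantom")
}

tiny_geometry <- function(n = 8, nz = n, n_angles = 12, voxel = 4.8) {
  acquisition_geometry(n_angles = n_angles, nu = n, nv = nz,
                       pitch_mm = voxel)
}

# memoise expensive fixtures across test files within one run
fixture_env <- new.env(parent = emptyenv())
fixture <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# NEMA phantom resampled to the reconstruction grid used by the heavier tests
nema_recon_phantom <- function(tc_background = 0) {
  key <- paste0("nema_", tc_background)
  fixture(key, resample_phantom(
    make_nema_iq(tc_background = tc_background, ho_spheres = 0.8, voxel = 2),
    6.4, n_out = c(48, 48, 40)))
}

nema_recon_geometry <- function(n_angles = 60) {
  acquisition_geometry(n_angles = n_angles, nu = 48, nv = 40, pitch_mm = 6.4)
}
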
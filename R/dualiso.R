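# Three-step dual-isotope reconstruction:
#   1. Tc-99m OSEM on the 140-keV window, Ho-166 crosstalk corrected by the
#      k-factor-scaled 170-keV scatter window;
#   2. Monte Carlo simulation of Tc-99m downscatter into the 81-keV window
#      from the step-1 image;
#   3. Ho-166 OSEM on the 81-keV window with the downscatter estimate (plus
#      the Ho self-scatter model) as additive scatter.

#' Bundle a dual-isotope acquisition into a study
#'
#' @param proj `projection_set` containing all four windows (`ho81`,
#'   `sc118`, `tc140`, `sc170`). The 118-keV scatter window is validated and
#'   stored but unused by default.
#' @param phantom `voxel_phantom` on the reconstruction grid (material map
#'   stands in for the attenuation CT).
#' @param psf_tables Per-window PSF tables (built from the geometry when
#'   `NULL`).
#' @param tc_cfg,ho_cfg [recon_config()]s for the two reconstructions.
#' @param n_histories Histories for the downscatter / self-scatter
#'   simulations.
#' @param downscatter_seed,selfscatter_seed Seeds for the two Monte Carlo
#'   estimates.
#' @param refresh_every In `"additive"` mode, recompute the self-scatter
#'   estimate every this many OSEM iterations (`Inf`: once, from the
#'   iteration-1 estimate).
#' @param scatter_scale_mm Decay length of the broad scatter component in
#'   `"kernel"` mode.
#' @param self_scatter_mode How the isotopes' own scattered photons are
#'   modeled inside OSEM. `"kernel"` (default): a broad scatter component
#'   whose amplitude is calibrated per study by the Monte Carlo self-scatter
#'   estimate is folded into the system matrix, mirroring a Monte
#'   Carlo forward projector; `"additive"`: the Monte Carlo estimate enters
#'   as an additive term, rescaled to the window's count budget and
#'   refreshed every `refresh_every` iterations; `"none"`: primaries only.
#' @param det [detector_model()].
#' @return Object of class `dual_study`.
#' @export
dual_study <- function(proj, phantom, psf_tables = NULL,
                       tc_cfg = recon_config(), ho_cfg = recon_config(),
                       n_histories = 5e4, downscatter_seed = 11,
                       selfscatter_seed = 12, refresh_every = 5,
                       self_scatter_mode = c("kernel", "additive", "none"),
                       scatter_scale_mm = 60, det = detector_model()) {
  self_scatter_mode <- match.arg(self_scatter_mode)
  need <- c("ho81", "sc118", "tc140", "sc170")
  missing <- setdiff(need, names(proj$counts))
  if (length(missing)) {
    stop("missing window(s) in projection set: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(psf_tables)) psf_tables <- psf_tables_for(proj$geometry, det)
  structure(list(proj = proj, phantom = phantom, geom = proj$geometry,
                 psf_tables = psf_tables, tc_cfg = tc_cfg, ho_cfg = ho_cfg,
                 n_histories = n_histories,
                 downscatter_seed = downscatter_seed,
                 selfscatter_seed = selfscatter_seed,
                 refresh_every = refresh_every,
                 self_scatter_mode = self_scatter_mode,
                 scatter_scale_mm = scatter_scale_mm, det = det),
            class = "dual_study")
}

#' Monte Carlo estimate of Ho-166 self-scatter in the 81-keV window
#'
#' Expected 81-keV-window counts from everything in the Ho-166 spectrum
#' except the unscattered photopeak emission that the deterministic
#' projector already models: in-phantom scatter of the 81-keV line,
#' downscatter of the high-energy gammas, and the bremsstrahlung continuum.
#' Linear in the Ho image.
#'
#' @param ho_image Ho activity array (MBq/ml) or `activity_image`.
#' @param phantom `voxel_phantom` for grid and materials.
#' @param geom [acquisition_geometry()].
#' @param psf_tables Per-window PSF tables.
#' @param n_histories Photon histories.
#' @param seed RNG seed.
#' @param spectrum Ho emission spectrum (override to truncate lines or drop
#'   the continuum).
#' @param det [detector_model()].
#' @return A `scatter_estimate` for window `ho81`.
#' @export
ho_self_scatter_estimate <- function(ho_image, phantom,
                                     geom = acquisition_geometry(),
                                     psf_tables = NULL, n_histories = 5e4,
                                     seed = 12,
                                     spectrum = emission_spectrum("Ho166"),
                                     det = detector_model()) {
  if (inherits(ho_image, "activity_image")) ho_image <- ho_image$data
  stopifnot(all(ho_image >= 0))
  set.seed(seed)
  if (is.null(psf_tables)) psf_tables <- psf_tables_for(geom, det)
  if (sum(ho_image) <= 0) {
    return(scatter_estimate("ho81",
                            array(0, dim = c(geom$nu, geom$nv, geom$n_angles))))
  }
  part <- mc_project(ho_image, phantom, spectrum, psf_tables["ho81"], geom,
                     n_histories, det = det, score_windows = "ho81",
                     skip_unscattered_direct = TRUE)
  scatter_estimate("ho81", part$ho81)
}

# Rescale a self-scatter shape to the count budget: in the 81-keV window the
# non-primary Ho contribution dominates the primaries by far, so a naive
# alternation between reconstruction and scatter re-estimation oscillates.
# The Monte Carlo provides the scatter *shape* and the scatter-to-primary
# count ratio rho = total(S x) / total(A x) (a property of the spectrum and
# geometry, insensitive to the scale of x); the scatter total is then pinned
# to rho/(1+rho) of the counts left after downscatter subtraction.
scale_self_scatter <- function(self, model, x, y_total, down_total) {
  s_tot <- sum(self$counts)
  if (s_tot <= 0) return(self)
  p_tot <- sum(forward_project(x, model))
  rho <- s_tot / max(p_tot, 1e-12)
  target <- max(y_total - down_total, 0) * rho / (1 + rho)
  scatter_estimate(self$window, self$counts * target / s_tot)
}

# uniform initial estimate restricted to the body support (air voxels start
# and therefore stay at zero under the multiplicative update)
support_init <- function(phantom) {
  init <- array(0, dim = phantom$dim)
  init[phantom$materials != 0L] <- 1e-6
  init
}

# step 3 (also the Ho-only reconstruction when downscatter is NULL/zero)
reconstruct_ho_step <- function(study, downscatter = NULL) {
  geom <- study$geom
  base <- if (is.null(downscatter)) {
    array(0, dim = c(geom$nu, geom$nv, geom$n_angles))
  } else {
    downscatter$counts
  }
  run_iso_step(study, "ho81", "Ho166", base, study$ho_cfg,
               ho_self_scatter_estimate, study$selfscatter_seed)
}

#' Monte Carlo estimate of Tc-99m self-scatter in the 140-keV window
#'
#' Expected 140-keV-window counts from scattered Tc-99m photons (everything
#' except the unscattered photopeak component that the deterministic
#' projector models). The reference system embeds this scatter in its Monte
#' Carlo forward projector; with the deterministic-primary projector it
#' enters the reconstruction as an additive term alongside the
#' energy-window estimate of the Ho-166 crosstalk.
#'
#' @inheritParams ho_self_scatter_estimate
#' @param tc_image Tc activity array (MBq/ml) or `activity_image`.
#' @return A `scatter_estimate` for window `tc140`.
#' @export
tc_self_scatter_estimate <- function(tc_image, phantom,
                                     geom = acquisition_geometry(),
                                     psf_tables = NULL, n_histories = 5e4,
                                     seed = 13,
                                     spectrum = emission_spectrum("Tc99m"),
                                     det = detector_model()) {
  if (inherits(tc_image, "activity_image")) tc_image <- tc_image$data
  stopifnot(all(tc_image >= 0))
  set.seed(seed)
  if (is.null(psf_tables)) psf_tables <- psf_tables_for(geom, det)
  if (sum(tc_image) <= 0) {
    return(scatter_estimate("tc140",
                            array(0, dim = c(geom$nu, geom$nv, geom$n_angles))))
  }
  part <- mc_project(tc_image, phantom, spectrum, psf_tables["tc140"], geom,
                     n_histories, det = det, score_windows = "tc140",
                     skip_unscattered_direct = TRUE)
  scatter_estimate("tc140", part$tc140)
}

# Self-scatter-to-primary count ratio rho = total(S x) / total(A x),
# measured by Monte Carlo on a bootstrap estimate; a property of the
# spectrum, window and object geometry, insensitive to the scale of x.
self_scatter_ratio <- function(raw, model, x) {
  s_tot <- sum(raw$counts)
  if (s_tot <= 0) return(0)
  s_tot / max(sum(forward_project(x, model)), 1e-12)
}

# generic OSEM step for one isotope window with the three self-scatter modes
run_iso_step <- function(study, window_label, isotope, base_scatter,
                         cfg, self_fun, self_seed) {
  geom <- study$geom
  model <- system_model(study$phantom, geom, geom$windows[[window_label]],
                        psf_table = study$psf_tables[[window_label]],
                        isotope = isotope, det = study$det)
  init <- support_init(study$phantom)
  base <- scatter_estimate(window_label, base_scatter)
  if (study$self_scatter_mode == "none") {
    return(list(image = osem(study$proj, model, base, cfg, init = init),
                self_scatter = NULL))
  }
  # bootstrap estimate of the activity support drives the Monte Carlo
  boot <- osem(study$proj, model, base,
               recon_config(1, cfg$n_subsets, cfg$k_factor), init = init)
  raw <- self_fun(boot, study$phantom, geom, study$psf_tables,
                  study$n_histories, seed = self_seed, det = study$det)
  if (study$self_scatter_mode == "kernel") {
    rho <- self_scatter_ratio(raw, model, boot$data)
    model_eff <- system_model(study$phantom, geom,
                              geom$windows[[window_label]],
                              psf_table = study$psf_tables[[window_label]],
                              isotope = isotope, det = study$det,
                              scatter_amplitude = rho,
                              scatter_scale_mm = study$scatter_scale_mm)
    return(list(image = osem(study$proj, model_eff, base, cfg, init = init),
                self_scatter = raw, scatter_amplitude = rho))
  }
  # additive mode: budget-rescaled estimate, refreshed in blocks
  y_total <- sum(study$proj$counts[[window_label]])
  base_total <- sum(base$counts)
  self <- scale_self_scatter(raw, model, boot$data, y_total, base_total)
  x <- NULL
  snapshots <- list()
  done <- 0
  while (done < cfg$n_iterations) {
    block <- min(study$refresh_every, cfg$n_iterations - done)
    if (!is.finite(block)) block <- cfg$n_iterations - done
    est <- osem(study$proj, model,
                scatter_estimate(window_label, base$counts + self$counts),
                recon_config(block, cfg$n_subsets, cfg$k_factor,
                             save_iterations = cfg$save_iterations),
                init = if (is.null(x)) init else x)
    x <- est$data
    if (cfg$save_iterations) snapshots <- c(snapshots, est$snapshots)
    done <- done + block
    if (done < cfg$n_iterations) {
      raw <- self_fun(x, study$phantom, geom, study$psf_tables,
                      study$n_histories, seed = self_seed, det = study$det)
      self <- scale_self_scatter(raw, model, x, y_total, base_total)
    }
  }
  est$iterations <- cfg$n_iterations
  est$snapshots <- if (cfg$save_iterations) snapshots
  list(image = est, self_scatter = self)
}

# step 1: Tc OSEM; Ho crosstalk corrected by the TEW estimate, Tc in-patient
# scatter by the study's self-scatter mode
reconstruct_tc_step <- function(study) {
  geom <- study$geom
  tew <- tew_scatter_estimate(study$proj, k_factor = study$tc_cfg$k_factor,
                              width_correction = study$tc_cfg$width_correction,
                              photopeak = geom$windows$tc140,
                              upper = geom$windows$sc170)
  res <- run_iso_step(study, "tc140", "Tc99m", tew$counts, study$tc_cfg,
                      tc_self_scatter_estimate,
                      study$selfscatter_seed + 1L)
  list(image = res$image, tew = tew, self_scatter = res$self_scatter)
}

#' Three-step dual-isotope reconstruction
#'
#' Runs the full pipeline on a [dual_study()]: Tc-99m OSEM with the
#' k-factor-scaled 170-keV window as additive scatter, Monte Carlo
#' simulation of the resulting Tc image's downscatter into the 81-keV
#' window, and Ho-166 OSEM with that downscatter (plus Ho self-scatter) as
#' additive scatter. All intermediates are returned.
#'
#' @param study A `dual_study`.
#' @return List with `tc_image`, `ho_image`, and `intermediates` (the TEW
#'   scatter estimate, the downscatter estimate, and the final self-scatter
#'   estimate).
#' @export
reconstruct_dual <- function(study) {
  tc <- reconstruct_tc_step(study)
  downscatter <- simulate_downscatter(tc$image, study$phantom, study$geom,
                                      study$psf_tables, study$n_histories,
                                      seed = study$downscatter_seed,
                                      det = study$det)
  ho <- reconstruct_ho_step(study, downscatter)
  list(tc_image = tc$image, ho_image = ho$image,
       intermediates = list(tew = tc$tew,
                            tc_self_scatter = tc$self_scatter,
                            downscatter = downscatter,
                            self_scatter = ho$self_scatter))
}

#' Ho-166-only reconstruction (no Tc downscatter term)
#'
#' Step 3 of the pipeline with a zero downscatter estimate; used as the
#' single-isotope reference. With identical seeds, a dual reconstruction of
#' a study whose Tc windows are empty reproduces this result exactly.
#'
#' @param study A `dual_study`.
#' @return List with `ho_image` and `intermediates`.
#' @export
reconstruct_ho_only <- function(study) {
  ho <- reconstruct_ho_step(study, downscatter = NULL)
  list(ho_image = ho$image,
       intermediates = list(self_scatter = ho$self_scatter))
}
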
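# OSEM reconstruction with an additive scatter term, the energy-window
# (k-factor) scatter estimator, and cross-calibration.

#' Reconstruction configuration
#'
#' @param n_iterations Full OSEM iterations (default 20).
#' @param n_subsets Ordered subsets (default 8); must divide the number of
#'   projection angles.
#' @param k_factor Scale applied to the upper scatter window in
#'   [tew_scatter_estimate()] (default 0.93).
#' @param width_correction Additionally scale `k` by the photopeak/upper
#'   window width ratio in keV (0.93 becomes about 0.96 for the 140/170
#'   window pair).
#' @param save_iterations Keep a per-iteration snapshot stack.
#' @param nonneg_floor Lower clamp applied to the estimate (keeps strictly
#'   positive voxels updatable).
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(n_iterations = 20, n_subsets = 8, k_factor = 0.93,
                         width_correction = FALSE, save_iterations = FALSE,
                         nonneg_floor = 0) {
  stopifnot(n_iterations >= 1, n_subsets >= 1, k_factor > 0)
  structure(list(n_iterations = n_iterations, n_subsets = n_subsets,
                 k_factor = k_factor, width_correction = width_correction,
                 save_iterations = save_iterations,
                 nonneg_floor = nonneg_floor),
            class = "recon_config")
}

#' Energy-window scatter estimate from an upper scatter window
#'
#' Scatter under the photopeak is estimated as `k` times the counts recorded
#' in the upper scatter window, bin by bin. With `width_correction` the
#' factor is additionally scaled by the ratio of photopeak to upper window
#' widths in keV, accounting for the per-keV normalization of the windows.
#'
#' @param upper_window_proj Counts array of the upper scatter window, or a
#'   `projection_set` together with `upper_label`.
#' @param k_factor Scalar `k` (default 0.93).
#' @param width_correction Apply the window-width ratio (default `FALSE`).
#' @param photopeak,upper [energy_window()]s used for the width ratio
#'   (defaults: 140 keV/15% and 170 keV/12%).
#' @param upper_label Window label when a `projection_set` is given.
#' @param target_window Label stored on the returned estimate.
#' @return A `scatter_estimate`.
#' @export
tew_scatter_estimate <- function(upper_window_proj, k_factor = 0.93,
                                 width_correction = FALSE,
                                 photopeak = energy_window("tc140", 140, 0.15),
                                 upper = energy_window("sc170", 170, 0.12),
                                 upper_label = "sc170",
                                 target_window = "tc140") {
  stopifnot(k_factor > 0)
  if (inherits(upper_window_proj, "projection_set")) {
    upper_window_proj <- upper_window_proj$counts[[upper_label]]
  }
  k <- effective_k_factor(k_factor, width_correction, photopeak, upper)
  scatter_estimate(target_window, k * upper_window_proj)
}

#' Effective k-factor including the optional window-width correction
#'
#' @inheritParams tew_scatter_estimate
#' @return The scalar actually applied to the upper-window counts.
#' @export
effective_k_factor <- function(k_factor = 0.93, width_correction = TRUE,
                               photopeak = energy_window("tc140", 140, 0.15),
                               upper = energy_window("sc170", 170, 0.12)) {
  if (!width_correction) return(k_factor)
  k_factor * (photopeak$hi - photopeak$lo) / (upper$hi - upper$lo)
}

#' OSEM reconstruction with additive scatter
#'
#' Ordered-subsets EM for Poisson projection data `y` with forward model
#' `A x + s`: per subset, `x <- x / (A^T 1) * A^T (y / (A x + s))`. Subsets
#' interleave the angles (1, 1+n, 1+2n, ...). With one subset this is exactly
#' MLEM. Nonnegativity is preserved by construction; bins where the
#' denominator and the data are both zero contribute a unit ratio, while a
#' zero denominator under positive data raises a data-inconsistency warning.
#'
#' @param proj `projection_set` (or a bare counts array) for the photopeak
#'   window being reconstructed.
#' @param model [system_model()] for that window.
#' @param scatter Optional `scatter_estimate` (additive term `s`), zero when
#'   `NULL`.
#' @param cfg [recon_config()].
#' @param window Window label to pull from the projection set.
#' @param init Initial estimate (default: uniform positive image).
#' @return An `activity_image`: `data` (MBq/ml scale of the model), plus the
#'   iteration count, configuration, and optional `snapshots` list.
#' @export
osem <- function(proj, model, scatter = NULL, cfg = recon_config(),
                 window = model$window$label, init = NULL) {
  y <- if (inherits(proj, "projection_set")) proj$counts[[window]] else proj
  if (is.null(y)) stop("window ", window, " not present in projection set")
  n_ang <- model$geom$n_angles
  if (n_ang %% cfg$n_subsets != 0) {
    stop("number of angles must be divisible by n_subsets")
  }
  s <- if (is.null(scatter)) 0 * y else scatter$counts
  stopifnot(all(dim(y) == c(model$dim[1], model$dim[3], n_ang)))

  subsets <- lapply(seq_len(cfg$n_subsets), function(i)
    seq(i, n_ang, by = cfg$n_subsets))
  sens <- lapply(subsets, function(ang)
    back_project(array(1, dim = c(model$dim[1], model$dim[3], length(ang))),
                 model, angles = ang))

  x <- if (is.null(init)) array(1e-6, dim = model$dim) else init
  snapshots <- if (cfg$save_iterations) vector("list", cfg$n_iterations)
  warned <- FALSE
  for (it in seq_len(cfg$n_iterations)) {
    for (si in seq_along(subsets)) {
      ang <- subsets[[si]]
      ax <- forward_project(x, model, angles = ang) + s[, , ang, drop = FALSE]
      ysub <- y[, , ang, drop = FALSE]
      ratio <- ysub / ax
      zero_den <- ax <= 0
      if (any(zero_den)) {
        bad <- zero_den & ysub > 0
        if (any(bad) && sum(ysub[bad]) > 1e-6 * sum(ysub) && !warned) {
          warning("data-inconsistency: positive counts where the forward ",
                  "model is zero")
          warned <- TRUE
        }
        ratio[zero_den] <- 1
      }
      upd <- back_project(ratio, model, angles = ang)
      pos <- sens[[si]] > 0
      x[pos] <- x[pos] * upd[pos] / sens[[si]][pos]
      x[x < cfg$nonneg_floor] <- cfg$nonneg_floor
    }
    if (cfg$save_iterations) snapshots[[it]] <- x
  }
  structure(list(data = x, voxel_mm = model$voxel_mm, window = window,
                 iterations = cfg$n_iterations, config = cfg,
                 calibration = 1, snapshots = snapshots),
            class = "activity_image")
}

#' @export
print.activity_image <- function(x, ...) {
  cat(sprintf("<activity_image %s: %s, %d iterations, total %.3f MBq>\n",
              x$window, paste(dim(x$data), collapse = "x"), x$iterations,
              sum(x$data) * prod(x$voxel_mm) / 1000))
  invisible(x)
}

#' Apply a cross-calibration factor to a reconstruction
#'
#' @param image An `activity_image`.
#' @param factor Positive scalar; recorded in the image provenance.
#' @return The scaled `activity_image`.
#' @export
apply_calibration <- function(image, factor) {
  stopifnot(factor > 0)
  image$data <- image$data * factor
  if (!is.null(image$snapshots)) {
    image$snapshots <- lapply(image$snapshots, function(s)
      if (is.null(s)) NULL else s * factor)
  }
  image$calibration <- image$calibration * factor
  image
}

#' Poisson log-likelihood of projection data under the model
#'
#' `sum(y log(Ax+s) - (Ax+s))` ignoring the data-only constant; used to
#' verify the monotonicity of MLEM.
#'
#' @param image Activity array or `activity_image`.
#' @param proj Counts array or `projection_set`.
#' @param model [system_model()].
#' @param scatter Optional `scatter_estimate`.
#' @param window Window label.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(image, proj, model, scatter = NULL,
                           window = model$window$label) {
  y <- if (inherits(proj, "projection_set")) proj$counts[[window]] else proj
  ax <- forward_project(image, model)
  if (!is.null(scatter)) ax <- ax + scatter$counts
  ok <- ax > 0
  sum(y[ok] * log(ax[ok]) - ax[ok]) - sum(ax[!ok])
}
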
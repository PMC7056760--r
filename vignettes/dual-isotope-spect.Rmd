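---
title: "Dual-isotope Ho-166/Tc-99m SPECT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-isotope Ho-166/Tc-99m SPECT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(duospect)
```

## The problem

In liver radioembolization with Ho-166 microspheres, a small scout dose is
imaged by SPECT to predict the treatment distribution. Adding Tc-99m stannous
phytate — a radiocolloid taken up only by healthy liver parenchyma — to the
same acquisition delineates the healthy-liver compartment automatically and
without registration error. The price is spectral crosstalk: the two isotopes
contaminate each other's photopeak windows. Tc-99m (140.5 keV) reaches the
81-keV Ho-166 window through patient scatter, lead x-rays generated in the
collimator (the Pb K lines at 75-85 keV fall inside that window) and detector
resolution smearing; Ho-166 reaches the 140-keV window through downscatter of
its MeV gammas and its bremsstrahlung continuum.

`duospect` implements the complete simulation and reconstruction chain for
this protocol: voxelized digital phantoms, a Monte Carlo photon simulator
with energy-window scoring through point-spread-function (PSF) lookup
tables, a deterministic attenuated projector, OSEM with additive scatter,
the three-step crosstalk-corrected dual reconstruction, and quantitative
recovery analysis.

## The three-step reconstruction

1. **Tc-99m OSEM** on the 140-keV window (15% width). Ho-166 crosstalk is
   estimated by an upper scatter window at 170 keV (12% width) scaled by the
   packaged *k*-factor (0.93 on raw counts; `width_correction = TRUE`
   replaces it by `0.93 * 21 keV / 20.4 keV = 0.957`, i.e. 0.96, when the
   upper window is interpreted per keV — both readings are implemented
   because the choice is genuinely ambiguous, behind one flag).
2. **Downscatter simulation**: the step-1 Tc image is pushed through the
   Monte Carlo simulator and only the 81-keV window is scored. The resulting
   noise-free projection stack is the expected Tc contamination of the Ho
   window; it is linear in the Tc image.
3. **Ho-166 OSEM** on the 81-keV window (15% width) with the downscatter
   estimate as an additive term in the forward model
   `y ~ Poisson(A x + s)`.

The 118-keV scatter window is recorded, validated and stored, but takes no
part in the correction; its role in the protocol is undefined and it is left
dormant behind a hook.

## Photon physics

Emission spectra are packaged JSON constants: Tc-99m is a single 140.5-keV
line with 0.885 photons/decay; Ho-166 carries its 80.57-keV photopeak line
(0.0671/decay), the high-energy gammas at 1379, 1582 and 1662 keV, and a
coarse piecewise-constant bremsstrahlung continuum binned to the eight PSF
source-energy bands. Attenuation tables (water, PMMA, bone, air, agar) are
built from the Klein-Nishina total cross-section times electron density plus
an `E^-3` photoelectric term, anchored to standard values (water:
0.152 cm^-1 at 140 keV); they contain no K-edges and decrease monotonically
over 60-2000 keV, and are interpolated log-log. Coherent scatter and
in-patient fluorescence are omitted; photoelectric absorption ends a
history. Lead (with its 88-keV K-edge) is tabulated separately for the
collimator model only.

Compton scattering is sampled from the Klein-Nishina distribution by Kahn's
composition-rejection method; sampled energies always satisfy the kinematic
bounds `E/(1 + 2E/m_e c^2) <= E' <= E`. Transport through the voxelized
material map uses Woodcock (delta) tracking with analog interaction
sampling, survival biasing at interactions (the photon always scatters,
weighted by the Compton fraction), a 50-keV energy cutoff, at most 10
scatters, and a weight floor of 1e-4.

The camera's energy resolution defaults to 9.5% FWHM at 140 keV with
`FWHM(E) proportional to sqrt(E)` — typical NaI(Tl) values, chosen because
no measured resolution is packaged. The probability of recording a photon in
a window is the Gaussian mass of its smeared energy inside the window
bounds; this term produces the substantial single-scatter leakage of Tc-99m
into the 81-keV window (a 90.5-keV backscattered photon still has a ~20%
chance of being recorded below 87 keV).

## The collimator/detector PSF model

The detector response is a lookup table of 2-D kernels indexed by PSF source
energy (81, 95, 118, 140, 170, 300, 713, 1379 keV, selected by half-open
energy bands over 60-2000 keV with the lower edge inclusive) and
source-collimator distance (1, 5, 12, 24, 40 cm, linearly interpolated at
runtime and clamped outside). Kernels hold counts per emitted photon; sums
are channel efficiencies. Instead of transport-code-generated kernels, the
table is produced by a documented parameterized model of a medium-energy
parallel-hole collimator (hole diameter 2.94 mm, length 40.64 mm, septa
1.14 mm, hexagonal-hole shape factor 0.26, intrinsic resolution 3.8 mm):

* a Gaussian geometric core with `FWHM = d_hole (l_eff + d) / l_eff` and
  efficiency `(0.26 d/l_eff)^2 (d/(d+s))^2` (about 2.1e-4) — the *direct*
  kernel family used for in-window photons, weighted by the detection
  probability;
* a broad exponential septal-penetration tail with transmission
  `exp(-mu_Pb t)` along the minimal septal path `t = s l/(2d+s)` (6.6 mm:
  negligible at 140 keV, ~5% at 300 keV, ~65% at 1379 keV), multiplied by
  the crystal interaction probability, an in-window deposit fraction, and
  the solid angle subtended by the camera;
* a narrow near-field Gaussian representing lead K x-rays, active only for
  source energies above the Pb K-edge (88 keV) and windows covering
  72-88 keV.

Kernel support is truncated where the amplitude falls below 1e-6 of the
peak; the lost mass is reported in the table's `truncation_loss`, not
renormalized away.

Three amplitudes of this model cannot be derived from first principles at
this level of abstraction and were calibrated once against the count ratios
the physical system exhibits, then frozen as package defaults:
`xray_amplitude = 3e-4` reproduces C81/C140 of about 0.6 for a collimated
Tc-99m line source between PMMA slabs; `highe_deposit_factor = 2` and
`highe_xray_factor = 24` (both acting on source energies >= 226 keV, the
latter standing in for collimator/shield cascade physics of MeV photons)
reproduce the observed per-activity crosstalk factors of roughly 2 (81-keV
window) and 4 (140-keV window) between Tc-99m and Ho-166 on an
anthropomorphic torso geometry. All three live in `collimator_params()` and
can be overridden.

## Monte Carlo scoring

Every emission and every interaction vertex contributes deterministically to
every projection angle (forced detection): the contribution is the history
weight times the directional probability toward the detector (isotropic for
emissions, the Klein-Nishina phase function for scatter vertices, with the
kinematically consistent scattered energy), times the exit attenuation along
the ray, splatted into per-distance-knot accumulators and convolved once per
angle with the appropriate kernel. This estimator is used for *all*
simulated acquisitions; measurement noise is emulated by Poisson-sampling
the expectation (`poisson = TRUE`). Analog angular-acceptance sampling of a
collimated 120-view acquisition would waste essentially every history and
is not provided. Counts scale as activity x time per angle x photons per
decay; a single `sensitivity` constant absorbs any remaining
cross-calibration, and no dead time is modeled.

## The deterministic projector and OSEM

The in-window primary-photon system model is a rotation-based parallel-beam
projector: per angle the volume is rotated by a sparse bilinear operator,
attenuated along the exit path at the window's center energy
(Beer-Lambert, half-voxel self-attenuation), pooled into depth groups
(default 8) that share one distance-interpolated direct kernel, and
convolved via cached FFTs. The back projector applies the same pieces in
reverse with the transposed rotation; because the kernels are symmetric the
pair is adjoint to floating precision, verified against dense matrix
probing. The photopeak line's detection probability is folded into the
count scale so projector and simulator agree absolutely.

OSEM uses interleaved subsets (angles 1, 1+n, 1+2n, ...; the ordering is a
package choice), a uniform initial estimate restricted to the body support,
and the update `x <- x / (A^T 1) * A^T (y / (A x + s))`. Division guards:
bins with a zero denominator and zero data contribute a unit ratio; positive
data over a zero denominator raises a data-inconsistency warning. With one
subset the iteration is exactly MLEM (bit-identical), the Poisson
log-likelihood is non-decreasing on noise-free data, and counts are
conserved on uniform-sensitivity instances.

## Handling each isotope's own scatter

The reference reconstruction embeds all spectrum contributions in a Monte
Carlo forward projector. Splitting that into "deterministic primaries plus
additive scatter" is numerically delicate for Ho-166: in the 81-keV window
the non-primary contribution (in-patient scatter of the photopeak line,
high-energy downscatter, bremsstrahlung) carries roughly ten times the
counts of the unscattered primaries. Two consequences were observed and
drove the design:

* naively alternating reconstruction and scatter re-estimation oscillates
  (the additive term overshoots, the estimate collapses, and vice versa);
* with an additive term covering ~90% of the counts, MLEM's nonnegativity
  produces a large positive noise bias.

The default (`self_scatter_mode = "kernel"`) therefore folds the isotope's
own scatter into the system matrix, as the reference system does: each depth
kernel gains a broad exponential component (decay length
`scatter_scale_mm = 60`) whose amplitude is the scatter-to-primary count
ratio `rho = total(S x)/total(A x)` measured by the package's own Monte
Carlo self-scatter estimate on a one-iteration bootstrap image. `rho` is a
ratio of two quantities linear in `x` and is therefore insensitive to the
bootstrap's scale. The additive pathway (`"additive"`) remains available;
it stabilizes the alternation by pinning the scatter total to
`rho/(1+rho)` of the window's counts after downscatter subtraction and
refreshing the shape every `refresh_every` iterations (default 5). The Tc
step uses the same machinery for Tc self-scatter in the 140-keV window, on
top of the energy-window estimate of the Ho crosstalk.

## Phantoms

All study conditions are generated, not measured:

* **NEMA IQ**: six spheres (10, 13, 17, 22, 28, 37 mm; 0.52-26.5 ml) on the
  standard 114.4-mm pitch circle (taken from the NEMA layout; the source
  protocol does not print it), default 0.8 MBq/ml Ho-166; an
  elliptic-cylinder background compartment holding the Tc-99m concentration
  (0, 6 or 11 kBq/ml), reduced to 5.5 L by an inert agar fill entered from
  one axial end so the sphere plane stays in solution; a central 50-mm air
  insert mimics the lung cylinder. The true torso-shaped NEMA shell is
  approximated by the ellipse — recovery analysis is insensitive to the
  shell's exact outline.
* **Cylinder**: 6.3 L, homogeneous 50 MBq Tc-99m (7.94 kBq/ml).
* **Line source**: a one-voxel Tc-99m line between two 40 x 40 x 10 cm^3
  PMMA slabs; the slab material can be switched to water to study the
  attenuation-model mismatch the protocol itself suffers from.
* **Torso**: elliptic water body, a 1200-ml liver compartment at 34 kBq/ml
  Tc-99m, and a 130-ml insert at 53 MBq Ho-166 (0.41 MBq/ml). The stated
  total added Tc activity (35 MBq) and the caption concentration (34 kBq/ml x
  1200 ml = 40.8 MBq) disagree in the source material; the generator
  follows the concentration and exposes both numbers.

Generation defaults to 2-mm voxels (sphere membership by voxel-center test;
voxelized totals converge to the analytic activities as voxels shrink) with
volume-weighted resampling to the reconstruction grid. Phantoms are
deterministic given their configuration.

What the generators do *not* emulate: count-rate effects (dead time,
pile-up), breathing motion, CT-number-derived material maps (materials are
labeled exactly), detector non-uniformity, and the torso-shaped NEMA shell.
Passing tests therefore demonstrate the internal consistency and the
qualitative crosstalk behavior of the method, not camera-specific absolute
accuracy.

## VOI analysis

VOIs are placed automatically by maximizing the summed mean VOI activity of
the known sphere layout over a rigid offset (coarse lexicographic-tie-break
grid search, then Nelder-Mead refinement; sub-voxel sampling by trilinear
interpolation over a deterministic spiral lattice). Matched VOIs report mean
concentration over true concentration; dilated VOIs (+20 mm diameter)
report total VOI activity over true sphere activity — the only
self-consistent reading of mixing mean- and total-based recovery, and it is
applied consistently. Recovery is reported to 0.1%. Dilation sweeps are
limited to +40 mm: beyond that, VOIs overlap neighboring spheres, and the
package raises an error. VOIs smaller than a voxel fall back to a trilinear
point sample at the VOI center.

## Problem sizes used by the tests

The test suite and the acceptance script run scaled-down instances chosen as
the package's own verification sizes: reconstruction grids of 40-48 voxels
per transaxial side at 6.4-7.68 mm, 32-60 projection angles in 4 subsets of
8-15, 1e5 histories for acquisitions and 5e4 for scatter estimates, and
16-50 OSEM iterations. The protocol-scale configuration (4.8-mm grid, 120
angles in 8 subsets of 15, 20-100 iterations) is the package default for
real use. At the verification sizes the qualitative structure of the
recovery experiments is reproduced: monotone size-dependent recovery,
slower convergence of small spheres under Tc-99m background, and
dilated-VOI recovery at or above matched-VOI recovery.

## Known limitations

* The PSF model is an analytic stand-in: absolute crosstalk magnitudes
  inherit its calibration (three amplitudes matched to reported count-ratio
  scales) and should not be read as camera-accurate.
* The bremsstrahlung continuum is coarse (eight bands, package constants).
* Attenuation is evaluated at the window center energy inside the
  projector, and scattered-photon exit attenuation uses the scattered
  energy — both standard simplifications.
* Small-sphere recovery at the scaled-down verification sizes is lower than
  at protocol scale; the orderings, not the absolute values, are the tested
  claims.
* No dead time, no motion, no DICOM/Interfile ingestion.
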
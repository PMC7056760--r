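# duospect

Simulation and quantitative reconstruction for simultaneous
**Ho-166 / Tc-99m dual-isotope SPECT**, the imaging protocol behind
automatic liver dosimetry in Ho-166 radioembolization: a Ho-166 scout dose
maps the expected microsphere distribution while Tc-99m stannous phytate
labels healthy liver parenchyma in the same acquisition. The two isotopes
contaminate each other's photopeak windows — Tc-99m (140.5 keV) reaches the
81-keV Ho-166 window through patient scatter, collimator lead x-rays and
resolution smearing; Ho-166 reaches the 140-keV window through downscatter
of its MeV gammas and bremsstrahlung — and this package implements the
crosstalk-corrected reconstruction chain end to end, for physicists who
want to study or extend the protocol on digital phantoms.

## What is inside

* **Phantoms** — voxelized activity + material maps for the NEMA IQ phantom
  (six spheres, 10-37 mm, on the 114.4-mm ring; reduced 5.5-L background),
  a 6.3-L cylinder, a Tc-99m line source between PMMA slabs, and an
  anthropomorphic torso with a 1200-ml liver and a 130-ml Ho insert.
* **Physics** — packaged emission spectra (Ho-166 lines + bremsstrahlung
  continuum; Tc-99m 140.5 keV), Klein-Nishina Compton sampling, log-log
  interpolated attenuation tables, Gaussian energy-window detection
  probabilities.
* **Monte Carlo simulator** — Woodcock tracking through the material map
  with forced-detection scoring into per-window projections via
  energy- and distance-indexed PSF lookup tables (8 source energies x 5
  distances, runtime-interpolated), including a parameterized
  medium-energy-collimator model with septal penetration and lead x-ray
  components.
* **Reconstruction** — rotation-based attenuated projector with
  distance-dependent PSF and exact adjoint; OSEM with additive scatter
  (`y ~ Poisson(Ax + s)`, update `x <- x/(A^T 1) * A^T[y/(Ax+s)]`); the
  energy-window (*k*-factor) scatter estimate; and the three-step dual
  reconstruction: Tc OSEM with *k*-scaled 170-keV window, Monte Carlo
  simulation of the Tc image's downscatter into the 81-keV window, and Ho
  OSEM with that downscatter as additive scatter.
* **Analysis** — automatic VOI placement, matched and dilated (+20 mm)
  recovery coefficients, convergence curves, dilation sweeps, line
  profiles, and the crosstalk count-ratio arithmetic (at a 5:1 Ho:Tc
  activity ratio the 81-keV window splits 5:2 and the 140-keV window 5:4).

A thin command-line wrapper ships at
`system.file("scripts", "duospect.R", package = "duospect")` with
subcommands `phantom | simulate | project | reconstruct | dual-recon |
analyze | psf-table`.

## Worked example

A scaled-down NEMA image-quality study: 0.8 MBq/ml Ho-166 spheres over an
11 kBq/ml Tc-99m background, simulated at 60 angles and reconstructed with
the three-step protocol (4 subsets; 10 Tc / 20 Ho iterations).

```r
library(duospect)

ph   <- resample_phantom(make_nema_iq(tc_background = 11), 6.4,
                         n_out = c(48, 48, 40))
geom <- acquisition_geometry(n_angles = 60, nu = 48, nv = 40, pitch_mm = 6.4)
proj <- simulate_projections(ph, geom, n_histories = 1e5, seed = 1,
                             poisson = TRUE)
proj
#> <projection_set: ho81=2.86e+06, sc118=7.71e+05, tc140=2.8e+06, sc170=3.6e+05 (Poisson sampled)>

st  <- dual_study(proj, ph, tc_cfg = recon_config(10, 4),
                  ho_cfg = recon_config(20, 4))
res <- reconstruct_dual(st)
res$ho_image
#> <activity_image ho81: 48x48x40, 20 iterations, total 50.842 MBq>

recovery_coefficients(res$ho_image, spec = voi_spec(dilation_mm = 20),
                      true_conc = 0.8)
#>   sphere diameter_mm voi_diameter_mm    mean_conc recovery_pct
#> 1      1          10              30 0.0014537902          5.1
#> 2      2          13              33 0.0008800605          1.8
#> 3      3          17              37 0.0036071254          4.8
#> 4      4          22              42 0.0139691602         12.2
#> 5      5          28              48 0.1312596888         83.1
#> 6      6          37              57 0.3660488426        165.5
```

Reading the output: the 81-keV window records 2.86 M counts of which the
majority is Tc-99m downscatter — the correction chain removes it before the
Ho image is formed. The dilated-VOI recovery (total VOI activity as a
percent of the true sphere activity) rises with sphere size as spill-out
and slow convergence penalize small structures; the Tc-99m background
inflates the apparent activity of the large spheres and the image total
(50.8 vs 39.7 MBq true here), the same accuracy loss the dual-isotope
protocol exhibits on physical phantoms. Without Tc background the image
total is recovered to within a few percent.

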
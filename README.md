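# iscatsim

Simulation platform for interference microscopy of nanoparticles:
interferometric scattering (iSCAT), coherent bright-field (COBRI) and
dark-field imaging, for researchers who need camera-level predictions of what
a nanoparticle near a coverslip looks like — contrast levels, defocus ring
structure, illumination-angle effects — from first-principles electromagnetic
solutions rather than scalar PSF models.

## What it computes

The detected image is the interference of the reference beam (illumination
reflected at, or transmitted through, the substrate) with the light scattered
by the particle,

    I(x, y) ∝ | E'_ref(x, y) + E'_sca(x, y) |²,

and every stage of that chain is modelled vectorially:

* **Layer stacks** — Fresnel transfer matrices for planar media; total
  driving fields (incident + reflected) above the stack; Brewster-angle
  reference suppression.
* **Scattering engines** — point dipole (Clausius–Mossotti, with radiative
  correction), exact Mie theory, and a Galerkin boundary-element Maxwell
  solver (PMCHWT formulation, RWG edge basis, Duffy/Sauter–Schwab singular
  quadrature) for arbitrary triangulated particles: spheres, cubes, dimers,
  coated particles.  Substrate response enters through a far-field Fresnel
  interface correction, exact for point dipoles and accurate for particles
  up to ~50 nm.
* **Imaging** — the Richards–Wolf vectorial model of an aplanatic two-lens
  system (sine condition, energy conservation along ray bundles, paraxial
  image side), with Jones-matrix back-focal-plane elements (waveplates,
  attenuators, beam blocks) and a Bessel-accelerated azimuthal integration
  that is free of coarse-grid artifacts.
* **Modalities** — full-field iSCAT/COBRI/dark-field images, contrast and
  phase maps (the iPSF for point-like particles), focal stacks,
  correlation-based focus estimation, Michelson contrast, Brewster-angle
  sweeps, partial longitudinal coherence, and confocal scanning excitation.

The boundary-element solver is validated against Mie theory (cross sections
and complex far-field amplitudes), the optical theorem, reciprocity and
mesh-convergence studies; the imaging chain against energy conservation, the
shift theorem and analytic Bessel kernels.  See the methods vignette
(`vignettes/interference-microscopy-methods.Rmd`) for the models, numerical
choices and their rationale.

## Worked example

A 55 nm gold sphere in air, 5 nm above a glass coverslip, illuminated from
below at 14° through the substrate (TM), imaged at NA 1.3 with the focal
plane 500 nm above the interface:

```r
library(iscatsim)

stack <- layer_stack(list(material_db("air"), material_db("glass")))
wave  <- plane_wave(517, theta = 14, polarization = "TM", direction = "up")
train <- optical_train(NA_ = 1.3, n = 1.5, n_prime = 1, mag = 133.33)

cfg <- microscope_config("iscat", stack, wave, train,
  scatterer = list(engine = "mie", diameter = 55, material = "Au",
                   position = c(0, 0, 32.5)),
  fov = 3900, npix = 61)

sim <- simulate_image(cfg, z_foc = 500)
ctr <- iscat_contrast(sim$camera, sim$ref, normalized = TRUE)

st <- focal_stack(cfg, seq(-1000, 1000, by = 500))
fc <- focus_correlate(st, st[[4]]$image)
```

which prints

```
reference intensity      : 0.0316
peak |scattered| / |ref| : 0.1767
normalized contrast range: [-0.182, 0.347]
Michelson contrast       : 0.2446
focus estimate for the z = +500 nm slice: +500 nm
```

Reading the numbers: the reference intensity 0.0316 is `|r_TM|²` of the
glass–air interface at 14° — only ~3 % of the illumination returns, which is
what makes the weak scattered field visible against it.  The scattered field
at its peak is ~18 % of the reference *amplitude*, so the interference term
dominates the pure scattering term and the normalized contrast (camera minus
reference, over reference) swings between −18 % and +35 % across the defocus
fringes.  The focus estimator recovers the focal position of a noiseless
query slice exactly.

Configurations can equally be described in YAML (`load_config()`; bundled
presets under `inst/extdata/presets/` cover gold/polystyrene spheres in
water, the coupled gold dimer, the Brewster sweep and a silver nanocube),
and a thin command-line front end is provided:

```sh
Rscript inst/cli/iscatsim simulate --config cfg.yaml --out out/
Rscript inst/cli/iscatsim sweep-brewster --config cfg.yaml --angles 38,40,41.6,43
Rscript inst/cli/iscatsim focus --stack out/ --query img.tiff
```

`simulate` writes one 32-bit float TIFF per focal plane plus a JSON run
manifest (config hash, version, seed, timings); identical configs and seeds
reproduce bitwise-identical outputs.

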
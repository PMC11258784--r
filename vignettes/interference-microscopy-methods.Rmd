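---
title: "Simulating interference microscopy: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating interference microscopy: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Interferometric scattering microscopy (iSCAT) detects a nanoparticle through
the interference between a reference beam — the illumination reflected at the
coverslip — and the faint field the particle scatters.  Coherent bright-field
microscopy (COBRI) is the transmissive counterpart, interfering the
transmitted illumination with the scattered light, and dark-field microscopy
images the scattered light alone.  Because the detected signal is an
*interference*, simulating it faithfully requires tracking complex field
amplitudes — with their absolute phases — from the illumination through the
scatterer, the substrate, and a high-NA imaging system, all the way to the
camera:

$$ I(x,y) \propto \left| \mathbf{E}'_\mathrm{ref}(x,y) +
   \mathbf{E}'_\mathrm{sca}(x,y) \right|^2 . $$

`iscatsim` implements this chain end to end: planar layer stacks with Fresnel
transfer matrices, three scattering engines (point dipole, Mie, and a Galerkin
boundary-element Maxwell solver for arbitrary triangulated particles), a
far-field interface correction for the substrate, and a fully vectorial
Richards–Wolf model of aplanatic imaging with optional Jones-matrix
manipulations in the back focal plane.

# Conventions

All phases follow from a single set of conventions, stated here once and
enforced by tests:

* time dependence $e^{-i\omega t}$; an upward travelling plane wave is
  $e^{+ikz}$; passive media have $\mathrm{Im}\,\varepsilon \ge 0$;
* the (top) interface of the layer stack is at $z = 0$, $z$ increases into
  the sample medium; the substrate and the detection path are below;
* lengths in nm and angles in degrees at the API surface;
* fields are dimensionless relative to a unit incident amplitude; magnetic
  fields satisfy $\mathbf{H} = n\,\hat k \times \mathbf{E}$ per plane-wave
  component;
* the TM Fresnel reflection is defined so that $r_\mathrm{TM} \to
  (n_1-n_2)/(n_1+n_2)$ at normal incidence, co-oriented with TE.  Textbooks
  differ here; with this choice the reflected TM basis vector is
  $-\hat p(\hat k_r)$, which is exactly what makes the total tangential
  fields continuous across the interface (a test asserts continuity to
  $10^{-12}$).

Two field representations are the currency between modules: *plane-wave
decompositions* $\mathbf{E}(\mathbf r) = \sum_j w_j\,
\boldsymbol\epsilon_j e^{ik\hat k_j\cdot(\mathbf r - \mathbf r_0)}$ for
illumination and reference beams, and *far fields*
$\mathbf{E}(\mathbf r) = \mathbf{F}(\hat r)\, e^{ikr}/r$ for scattered light,
sampled on a Gauss–Legendre ($\cos\theta$) × uniform ($\phi$) direction grid
(defaults $n_\theta = 50$, $n_\phi = 51$).  Amplitudes are stored in
Cartesian components so rotations are exact.  Shifting the expansion origin
by $\mathbf r_0$ multiplies each amplitude by $e^{+ik\hat r\cdot\mathbf r_0}$;
the sign of this phase is fixed not by convention but by an oracle test that
re-evaluates the shifted far field at fixed physical points.

# Scattering engines

**Point dipole.**  The induced moment is $\mathbf p = \alpha\,
\mathbf E_\mathrm{drive}$ with the Clausius–Mossotti polarizability
$\alpha = a^3(\varepsilon_p-\varepsilon_h)/(\varepsilon_p+2\varepsilon_h)$
(radiative correction optional, and on by default inside the image pipeline
so the optical theorem holds).  The driving field is the *total* field above
the stack: incident plus interface-reflected.

**Mie.**  The exact sphere solution, used both as an engine and as the
oracle that validates the boundary-element solver.  The far-field amplitude
is assembled frame-free from the scattering amplitudes $S_1, S_2$, so
arbitrary (complex) drive polarizations and tilted illumination work by
superposition of the drive's plane-wave components.

**Boundary elements.**  For arbitrary homogeneous particles the package
solves the Maxwell transmission problem with a Galerkin PMCHWT formulation:
tangential traces $\mathbf J = \hat n\times\mathbf H$ and $\mathbf M =
\hat n\times\mathbf E$ are expanded in divergence-conforming RWG edge
functions, and the combined system built from the single-layer ($T$) and
double-layer ($K$) boundary operators of the inside and outside media,

$$ \begin{pmatrix} \eta_1 T_1 + \eta_2 T_2 & K_1 + K_2 \\
                   K_1 + K_2 & -(T_1/\eta_1 + T_2/\eta_2) \end{pmatrix}
   \begin{pmatrix}\mathbf J\\ \mathbf M\end{pmatrix}
   = -\begin{pmatrix}\mathbf E_\mathrm{inc}^\mathrm{tan}\\
       \mathbf H_\mathrm{inc}^\mathrm{tan}\end{pmatrix}, $$

is solved directly (dense LU).  The combination of the interior and exterior
null-field identities cancels the trace jump terms, and the formulation is
free of interior resonances for dielectric and metallic particles.  The
scattered field in the host is then $\mathbf E = \eta_1 T_1(\mathbf J) +
K_1(\mathbf M)$, whose far-field limit is analytic in the observation
direction — the far-field amplitude accepts *complex* directions, which the
interface correction below exploits.  Coated particles are handled as two
nested closed surfaces carrying one unknown set each, coupled through the
shell operators; the degenerate limits (shell = host, shell = core) are
tested against Mie theory.

Numerical choices in the solver, in decreasing order of subtlety:

* *Touching-pair double-layer integrals.*  The Galerkin entries of $K$ for
  edge- and vertex-adjacent triangle pairs are finite only through a
  four-dimensional cancellation at the shared edge; computing the inner
  integral exactly and the outer one numerically diverges logarithmically
  there (we measured this).  These entries therefore use Duffy-type
  (Sauter–Schwab) 4-D transformations with tensor Gauss rules that scale the
  singularity out.  The self term of $K$ vanishes identically for flat
  triangles.
* *Singular single-layer integrals.*  The static kernel $1/4\pi R$ and its
  gradient are integrated analytically over the source triangle (closed-form
  potential integrals, validated against brute-force quadrature), the smooth
  remainder with a 6-point Dunavant rule.  Near pairs use a refined or
  edge-graded outer rule because the extracted inner integrals are edge
  singular.
* *Quadrature defaults.*  6-point degree-4 triangle rules; pairs closer than
  twice the combined circumradii take the singular path.
* *Mesh guards.*  A warning when the largest edge exceeds a fifth of the
  in-medium wavelength, and a 10 000-element budget cap (override allowed):
  beyond that the dense solve dominates runtime.

**Volume-matched sphere meshes.**  A flat-facet mesh inscribed in a sphere
carries a systematic volume deficit of order $h^2$.  Scattering observables
of small particles scale with the particle volume, so this geometric bias —
not the boundary-element solution error — dominates cross-section errors of
inscribed meshes (we measure an apparent order $\approx 1.9$ for it).
`icosphere()` therefore rescales its meshes to the exact sphere volume by
default.  With the volume matched, a low-contrast sphere (polystyrene in
water) sits at an error floor of a few $10^{-4}$ with no measurable slope,
while a high-index dielectric ($n = 2.4$) exposes the solver's own
convergence, with the cross-section error decaying at order $\approx 1.5$
in the mesh size — the order expected for this discretization.  The
convergence study in the acceptance suite uses the high-index sphere for
exactly this reason.

**Substrate handling.**  The solver kernels are always homogeneous-medium
kernels.  The substrate enters twice: exactly in the *driving* field
(incident + reflected above the stack), and through the far-field interface
correction `interface_correct()`, which combines every emission direction
with its Fresnel-reflected partner (two-path phase $2k_1 z_0\cos\theta$) and
maps downward directions through Snell refraction with the spectral factor
$n_2\cos\theta_2 / (n_1\cos\theta_1)$ and the height phase
$e^{ik_1 z_0\cos\theta_1}$.  The supercritical ("forbidden-light") band uses
the analytic continuation of the source amplitude to complex directions.
For a point dipole this construction is *exact* (the classical
dipole-above-interface far field; the two implementations agree to
$10^{-12}$), and for extended particles it neglects only the near-field
(evanescent) coupling between particle and substrate.  This is the package's
main physical approximation; it is accurate for particles up to roughly
50 nm near the interface, where the full-solver and dipole-model emission
patterns agree to better than a percent in shape, and degrades for larger
particles or larger gaps.

# Imaging

The aplanatic two-lens system is modelled with two Gaussian reference
spheres (sine condition $\sin\theta' = (f/f')\sin\theta$, magnification
$M = (n/n')(f'/f)$) and the paraxial image side ($\cos\theta'\approx 1$,
$f'\gg f$).  TE ($\hat\phi$) components keep their orientation, TM
($\hat\theta$) components rotate to the image-side radial direction; both
recombine into the Cartesian transverse components of the back focal plane,
where an optional Jones transform $\Pi(\theta,\phi)$ acts (waveplates,
attenuators, beam blocks — composable).  The energy factor
$\sqrt{n\cos\theta/n'}$ makes power conservation along ray bundles exact:
the integrated image-plane power equals the collected-cone power to well
below the 1 % test tolerance.

Two evaluation routes exist for far fields.  The *direct* route accumulates
the two-dimensional quadrature $\sum_j w_j\,(\cdot)\,
e^{ik_0 n \sin\theta_j\,\rho\cos(\phi_j-\varphi)}$ per pixel; at coarse
azimuthal sampling its integrand oscillates faster than the grid can follow
at large image radii, producing ring artifacts (a warning fires when the
estimated bandwidth exceeds the sampling).  The *Bessel* route performs a
discrete azimuthal Fourier transform and integrates each order analytically,
$\int_0^{2\pi} e^{im\phi} e^{iq\rho\cos(\phi-\varphi)} d\phi = 2\pi i^m
J_m(q\rho) e^{im\varphi}$, which is artifact-free at the default grid and
agrees with the refined direct quadrature to $10^{-3}$; it is the pipeline
default.  Truncation of the Fourier series is exposed but not needed at the
default grids.

Two normalization conventions tie everything together: the global phase of
the imaging integral is set to zero, and the intensity scale is fixed so a
unit-amplitude on-axis reference plane wave maps to unit image intensity.
The far-field and plane-wave routes are mutually consistent through the
Debye identity $\boldsymbol\epsilon(\hat k) = (ik/2\pi)\mathbf F(\hat k)$ —
including the factor $i$, which sets the *relative phase* between the imaged
reference and scattered beams and hence the sign structure of the iSCAT
contrast.  Image coordinates are returned object-referred (image coordinate
divided by $M$), so fields of view read in sample-plane nanometres.

The detection axis ($-z$ in laboratory coordinates for both iSCAT and COBRI)
maps onto the imaging $+z$ axis through a 180° rotation about $x$, applied
identically to reference and scattered fields, so their relative geometry
and phase are preserved.  Defocus is a shift of the expansion origin to the
focal plane, mirroring the defocusing procedure of the experiment.

# Assembled modalities

`simulate_image()` returns the total, reference and scattered camera images;
the identity $I = |\mathbf E'_\mathrm{ref}+\mathbf E'_\mathrm{sca}|^2$ holds
per pixel by construction and is asserted to $10^{-12}$.  COBRI shares the
entire pipeline with iSCAT — the illumination direction flips to 180° and
the transmitted rather than the reflected wave becomes the reference;
nothing else changes.  Dark-field requires a back-focal-plane block covering
the reference direction and rejects configurations without one.

Contrast maps come in two conventions, both exposed: raw
(`camera - |ref|^2`, the choice for Brewster-angle sweeps where the
reference itself varies) and normalized (divided by `|ref|^2`, rejected when
the reference is dark).  The per-pixel phase map is
$\phi = \arg(\mathbf E'_\mathrm{ref}\cdot\mathbf E'^*_\mathrm{sca})$.  For a
point-dipole scatterer the contrast map is the interferometric point spread
function (`ipsf()`).

Other assembled features, with their design choices:

* *Focus estimation* (`focus_correlate()`): two-dimensional Pearson
  correlation (explicit mean removal and variance normalization) between
  each simulated focal slice and a query image; ties break toward the
  smallest $|z|$.  Off-axis illumination gives a unique correlation maximum;
  on-axis, over- and under-focused images resemble their mirror slices and
  the correlation map shows the characteristic two-ridge crossing — both
  structures are asserted in the tests.
* *Brewster sweeps* (`brewster_sweep()`): TM-only; at
  $\theta_B = \arctan(n_2/n_1)$ the reference vanishes and the raw-image
  Michelson contrast $(I_\mathrm{max}-I_\mathrm{min})/(I_\mathrm{max}+
  I_\mathrm{min})$ peaks; small angle deviations tune the reference
  continuously.
* *Partial longitudinal coherence* (`partial_coherence()`): a weighted
  incoherent sum of per-wavelength intensities; weights must sum to one.
  Broadening the spectrum monotonically washes out the large-defocus rings.
* *Scanning excitation* (`scan_image()`): the focused beam is built in the
  substrate by angular-spectrum superposition (apodization
  $\sqrt{\cos\theta}$), split at the interface into the transmitted driving
  decomposition and the reflected, descanned reference, and translated
  across the sample; the detected signal is the camera intensity summed
  over a pinhole of one Airy unit ($0.61\lambda/\mathrm{NA}$), the standard
  confocal convention.
* *Detector model*: ideal intensity sampling; seeded Gaussian or Poisson
  noise is available for robustness studies (`add_noise()`).

# Materials and fixtures

Constant-index media (water 1.33, glass 1.5, polystyrene 1.59, air) and
tabulated metals are bundled.  The gold and silver tables are *approximate
transcriptions* of the standard published compilation of measured optical
constants (Johnson & Christy), linearly interpolated in wavelength and
accurate to about the second decimal in $n$ and $k$; quantities that depend
on the metal values inherit that uncertainty, and the corresponding
tolerances are set accordingly.  Queries outside the tabulated range are
rejected rather than extrapolated.

One configuration note: the bundled 55 nm gold-sphere presets place the
particle in *air* 5 nm above the glass substrate, following the body-text
description of that experiment; the corresponding tabulated setup parameters
can also be read as implying an aqueous sample.  The presets keep the
air-ambient reading.

# Problem sizes and what the tests show

The test suite builds all fixtures in code.  Unit tests run spheres at
80–320 elements, where the solver is already within a few percent of Mie;
the acceptance suite runs the 720-element-per-sphere gold dimer
(gap-midpoint field enhancement ≈ 6 under TM illumination at −20°), the
four-mesh convergence study, and the imaging and pipeline property checks at
the default direction grids.  These sizes were chosen so the whole suite
completes in minutes while each phenomenon is in its asymptotic regime.

What passing tests do and do not show: the synthetic configurations exercise
ideal plane waves, perfectly planar interfaces, homogeneous isotropic
materials and an aberration-free train.  Coverslip roughness, plasmonic
substrate enhancement, lens back-reflections and aberrations beyond the
back-focal-plane transform, near-field particle–substrate coupling, and
genuinely inhomogeneous particle materials are all outside the model, so
quantitative agreement with a given experiment additionally depends on those
effects being small or calibrated away.

# Known limitations

* The substrate acts on the scattered light only at the far-field level;
  near-field coupling to the interface (Sommerfeld integrals) is not
  included.  Expect growing errors for particles well above ~50 nm or
  strongly plasmonic gaps near the substrate.
* The dense direct solver limits practical meshes to a few thousand
  elements.
* `bem_nearfield()` uses regular quadrature and rejects points hugging the
  surface (within a quarter of the local edge length); near-singular field
  evaluation is not implemented.
* Evanescent components are dropped where they cannot contribute to imaging
  (propagating-wave imaging only), and the interpolating fallback of the
  interface correction ignores the supercritical band for far fields that
  carry no analytic amplitude function (all built-in engines carry one).
* The full FFT evaluation of the imaging integral is deliberately not
  implemented; the Bessel route covers the practical need and keeps image
  and direction grids independent.

# Reproducing the numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes the
system magnifications of the two documented experimental imaging setups
(40× objective with a 150 mm/500 mm relay; 60× with 75 mm/200 mm) from the
package's magnification model and writes them as JSON.  The acceptance test
file covers the remaining headline results — the glass–water Brewster angle,
the dimer gap enhancement, the mesh-convergence order and the pipeline-wide
conservation and consistency properties — each at the tolerance its physics
supports.
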
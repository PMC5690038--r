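---
title: "A film-derived virtual-source Monte Carlo model for the Gamma Knife Perfexion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A film-derived virtual-source Monte Carlo model for the Gamma Knife Perfexion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The Leksell Gamma Knife Perfexion focuses 192 Co-60 beams — eight movable
sectors of 24 sources arranged in five latitudinal rings — onto a common
focus, with per-sector apertures of 4, 8 or 16 mm. Detailed Monte Carlo
models of the collimator body require proprietary geometry. This package
implements the alternative: a *virtual source model* in which every source
is a point whose beam cross-section is an empirically measured 2D fluence
map on a cylindrical film surface, and whose remaining free parameters are
calibrated against the manufacturer's ring output factors. The goal of such
a model is patient-specific dose verification — reproducing planning-system
dose distributions within a few percent — not ab initio prediction of
machine data.

## The model

**Source representation.** Each source s is a point at distance $R_s$ from
the focus. Its beam is described by a fluence map on a cylinder of radius
$L = 113$ mm (226 mm diameter) wrapped around the focus: pixel intensities
$I_b$ with bixel area $S_b$. Film coordinates $(x_s, y_s)$ map to the
cylinder by $x = R\cos(x_s/R)$, $y = R\sin(x_s/R)$, $z = y_s$. A source
particle picks a bixel with probability $\propto I_b S_b$ (times the source
strength and the planned shot time), jitters uniformly within the bixel,
and travels from the source point through the sampled cylinder position.
The source point is placed on the ray through the intensity-weighted map
centroid, so every beam axis passes through the focus exactly. A shot
combines up to 8 sectors; sector $k$ reuses the sector-1 maps rotated by
$(k-1)\times 45^\circ$. All shots of a plan are merged into one sampling
distribution (weighted by shot time), which makes the run time independent
of the number of shots.

**Energy spectrum.** The two Co-60 lines at 1.17 and 1.33 MeV carry a
fraction `p_line` (default 0.8) of the emission; the remainder is an
exponential continuum (scale 0.3 MeV) of collimator-scattered photons
supported between the minimum single-scatter energy of the 1.33 MeV line
(1.33 − 1.12 = 0.21 MeV) and 1.33 MeV. The implied Compton edges, 1.12 MeV
for the 1.33 MeV line and 0.96 MeV for 1.17 MeV, follow from
$T_\mathrm{max} = E\,2\alpha/(1+2\alpha)$ and are asserted in the tests.
The same normalised spectrum serves all collimators. The true collimator
spectrum shape is not reproducible here; the parametric family is a
documented surrogate, acceptable because output factors are re-calibrated
downstream.

**Transport.** Photons undergo Compton scattering (Klein–Nishina sampling
by two-branch rejection), photoelectric absorption and pair production in
water, tracked through the voxel grid by Woodcock (majorant) delta-tracking
with a 50 keV absorption cutoff. Cross sections come from closed forms —
analytic Klein–Nishina, a parametric $E^{-3}$ photoelectric term anchored
at 50 keV, a small parametric pair term — committed as a plain-text table
and regenerated by `build_water_xsec()`; coherent scattering (no energy
transfer) is neglected. Electrons deposit energy along straight
continuous-slowing-down tracks driven by an embedded CSDA range table
(0.4367 g/cm² at 1 MeV), with a 200 keV threshold below which the residual
range is shorter than a voxel and energy is absorbed on the spot; lateral
electron scattering is out of scope. Optional crude bremsstrahlung
splitting exists but is off by default — its dosimetric effect in water at
these energies is small. Energy is conserved per history to floating
precision (emitted = deposited + escaped), and runs are bitwise
reproducible for a fixed (seed, batch partition): each batch owns an
independent deterministic random stream, so results do not depend on how
batches are scheduled.

**Scoring.** Full dose grids use analog energy deposition per 1 mm³ voxel
with history-batch variance (default 10 batches); the uncertainty summary
is the maximum relative standard error over voxels receiving at least 50%
of the maximum dose. Point doses for output factors use a track-length
collision-kerma estimator in a small box at the focus (1 voxel, or a 3³
region to cut variance): under charged-particle equilibrium at the centre
of these fields, collision kerma equals dose, and because calibration and
verification use the *same* estimator and region, any residual estimator
bias cancels in the output-factor ratios.

## Output factors and calibration

The ring output factor $f_{cr} = D_{cr}/D_{16,2}$ is the per-source central
dose rate of ring $r$ at collimator $c$ relative to ring 2 of the 16 mm
collimator. The collimator output factor combines rings weighted by the
per-sector source counts $N_r$:
$f_c = \sum_r N_r f_{cr} / \sum_r N_r f_{16,r}$.

**Ring multiplicities.** The counts $N_r$ are not given directly; they are
derived by exhaustive search over positive integer 5-vectors summing to 24
such that the weighted combination of the reference per-ring values
reproduces the reference totals for both the 4 mm and 8 mm collimators
within ±0.002. That search is degenerate — hundreds of vectors fall within
table rounding — so the package prefers the vector with the smallest ring
count spread (the physically sensible near-uniform distribution), breaking
remaining ties by score. The winner, (5, 5, 5, 5, 4), is frozen in the
default geometry and re-derived in the test suite.

**Calibration.** A film-based model cannot predict output factors ab
initio (the film measures dose, not fluence; buildup distorts it; source
and collimator axes are not perfectly aligned). Instead, two parameter sets
are adjusted until the simulated ring output factors match the manufacturer
reference table shipped with the package: the effective source-to-focus
distance for each (collimator, ring) — effective distances absorb
per-collimator differences, which is why each collimator gets its own
column — and a per-collimator mask threshold applied to the fluence maps
(pixels above the threshold are saturated to 1; the penumbra keeps its
relative intensity). The tuner is a deterministic coordinate descent: each
distance in turn is solved by a golden-section line search, warm-started by
inverting the analytic beam-spread factor $(1 - a_r/R_s)^2$ (with
$a_r = L/\sin\phi_r$ the focus-to-cylinder distance along the ray); mask
thresholds are touched only if ring residuals remain. The statistical
uncertainty of every output-factor estimate is forced below half the
tolerance (default tolerance 0.005 absolute) before comparison, and common
random numbers per knob keep the line search smooth. The 16 mm ring 2
distance is not identifiable (its output factor is a self-ratio of exactly
1) and stays nominal.

**Absolute dose.** The calibration factor $M$ converts Monte Carlo dose per
particle to Gy via $D_m = M/\Omega \times D_r \times T \times D_{MC}$,
where $D_m$ is the planning-system central dose of a reference 16 mm shot
(the 5 Gy-to-50%-isodose calibration prescription gives $D_m = 10$ Gy at
the focus), $D_r$ the dose rate, $T$ the time, and
$\Omega = \sum_s S_s/(R_s - L/\sin\theta_s)^2$ the solid-angle sum of the
fluence maps. Absolute accuracy is conditional on the supplied $D_m$.

## The synthetic film generator

The physical measurement — EBT2 film wrapped on the cylinder, one sector
irradiated per collimator, scanned at 240/150/96 dpi for 4/8/16 mm — is
replaced by a generator that emulates its geometry and its information
content. These defaults define the study conditions and were frozen during
model development, before the acceptance checks were written:

* **Ring geometry.** Film rows at z = 54, 73, 92, 111, 130 mm (polar angles
  64.4°…41.0° from the cylinder axis), chosen so that all 24 spots of one
  sector remain pairwise separated at the 1% intensity level even for the
  16 mm collimator — the property the larger 226 mm cylinder exists to
  provide. Nominal $R_s$ = 400 mm for every ring, the middle of the
  plausible 380–420 mm regime; the published source angles and fitted
  distances are proprietary, so these are documented stand-ins that the
  calibration step refines.
* **Spot shape.** Flat core of radius $(c/2)/m$ on the film — the aperture
  field size demagnified from focus to cylinder by
  $m = R_s/(R_s - a_r)$ — with an error-function penumbra
  (σ = 0.35/0.5/0.6 mm per collimator) and a $1/\sin\phi$ axial stretch
  from the oblique incidence on the cylinder. The projected core diameters
  therefore scale 4:8:16 at the focus.
* **Exposure levels.** Spot amplitude factorises into a per-collimator peak
  (0.88, 0.95, 1.0 — relative *primary* transmission, deliberately above
  the total output factors because small fields additionally lose
  phantom-scatter contribution, an effect the transport model produces by
  itself) and a per-ring brightness
  $\rho_r \propto f^c_r \sin\phi_r/(1-a_r/R_r)^2$ derived from the
  manufacturer reference column of the same collimator: the $\sin\phi$
  factor is the obliquity projection of beam flux onto the film, the
  quadratic factor the beam spread between film and focus. With these, the
  emulated machine's nominal ring output factors sit within ~0.02 of the
  reference and tuning makes only small, well-conditioned corrections
  (|ΔR_s| ≲ 12 mm, comfortably within the ≤ 2.4 cm spread reported for
  fitted effective distances).
* **Noise.** Additive Gaussian at 1% of the film maximum, emulating film
  and scanner grain.

**What the generator does not emulate:** film dose-response nonlinearity,
scanner artefacts (glass reflections, lateral response), bolus buildup,
cylinder mechanical tolerances, and source-to-collimator misalignment.
Passing the geometry-recovery tests (azimuths within 0.2°, axial positions
within 0.14 mm) therefore demonstrates the correctness of the analysis
pipeline under ideal film physics, not robustness to real-film artefacts.

## Image analysis pipeline

Films are smoothed by Perona–Malik anisotropic diffusion (4-neighbour
discrete scheme, conductance $g(\nabla I)=e^{-(\nabla I/K)^2}$, default
K = 0.1 on the normalised intensity scale, 5 iterations, step 0.2 — the
zero-flux boundaries conserve total intensity exactly, which the tests
assert), then opened with a disk structuring element (radius 2 px) to
remove specks; the exact diffusion parameters are configuration knobs, not
claims about the original analysis. Connected components above 2% of the
image maximum (a deterministic, logged segmentation level) become one
fluence map each — exactly 24 or the segmentation errors out — with the
dosimetric centre taken as the intensity-weighted centroid. Each map is
normalised to unit peak; the raw peak is kept as the source `strength` so
the absolute exposure level (which carries the collimator and ring output
information) survives normalisation and masking.

## Numerical choices and problem sizes

* Voxels are 1 mm³ water; phantoms are generated analytically (sphere,
  cylinder) or filled slice-wise from planar contours by an even-odd
  point-in-polygon test at voxel centres, with no partial-volume weighting.
* Dxx metrics interpolate the cumulative DVH linearly; the default bin
  width is 0.05 Gy.
* Commissioning simulations in this package's tests and acceptance script
  use 10⁵–10⁷ histories: ring output factors are estimated adaptively until
  their standard error is below tolerance/2 (typically 10⁵–10⁷ histories
  each), single-shot verification uses 10⁷ histories per collimator with
  the 3³-voxel central region, and the 1/√N uncertainty-scaling check spans
  N = 10⁵ to 1.6×10⁶ in a 4 cm sphere. These sizes were chosen so the full
  commissioning cycle runs on a single CPU in minutes; the scaling law they
  verify is what justifies extrapolating the uncertainty summary to the
  billion-history regime of production runs.
* The golden-section tolerance on effective distances is 0.7 mm, below the
  ~1 mm noise-equivalent of the output-factor estimates at the default
  tolerance.

## Known limitations

* Water-only media; no heterogeneity (bone, air) support.
* Straight-line electron transport without lateral spread slightly sharpens
  penumbrae relative to a condensed-history code with angular deflections.
* The parametric spectrum and closed-form cross sections are surrogates,
  adequate because output factors are re-calibrated; absolute fidelity of
  the continuum shape is not claimed.
* The generator's geometry is a stand-in, not vendor data: agreement with
  manufacturer output factors is achieved by calibration, as in any
  film-derived virtual source model, and validated by the *independent*
  single-shot route.
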
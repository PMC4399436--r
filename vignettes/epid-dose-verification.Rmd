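---
title: "EPID-based 3D dose verification: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EPID-based 3D dose verification: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidose)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made. Every quantitative
statement here is one that the test suite or `scripts/acceptance.R`
computes; nothing is quoted from external measurements.

## 1. The verification problem

A pre-treatment verification answers two questions: *was the plan delivered
as intended* (leaf positions, output), and *does the planning system's dose
algorithm handle this patient's anatomy correctly*. Uniform-phantom planar
QA conflates the two. The chain implemented here separates them:

1. each field is delivered in air and imaged with the portal imager;
2. the image is deconvolved into the incident energy fluence — a pure
   delivery measurement;
3. an independent dose algorithm (CCCS) recomputes 3D dose from that
   fluence, either in the patient density grid or in a water-overridden
   copy (`override_to_water()`), which removes heterogeneity-handling
   differences between algorithms and leaves delivery error only;
4. reconstructed and planned dose grids are compared with 3D gamma, DVHs
   and per-structure mean/max dose differences normalized to the
   prescription.

## 2. Fluence model

### Detector scatter kernel

The portal image of an in-air delivery is modeled as the incident fluence
convolved with a radially symmetric two-exponential kernel,
`K(d) = (1−c)·exp(−μ_S d) + c·exp(−μ_L d)`: a short-range term for the
energy spread of charged particles from first photon interactions, plus a
long-range term for scattered, bremsstrahlung and annihilation photons.
Because the beam is polyenergetic, `μ_S` and `μ_L` are *effective*
coefficients and are fitted per nominal energy rather than derived from
monoenergetic physics.

*Normalization.* The discrete kernel is normalized to unit sum; all
absolute scale lives in the single calibration factor `c_ad` obtained by
cross-calibrating the 10 cm × 10 cm reference field. This separates kernel
shape (a detector property) from calibration (a dosimetry chain property).

*Defaults.* `kernel_params()` defaults to `c = 0.05`, `μ_S = 1.6 /cm`,
`μ_L = 0.25 /cm`. These are plausible-scale placeholders, not measurements:
a small long-range fraction with a tail range of a few centimeters. They
were chosen once, for two reasons: the long-range fraction of real panel
glare kernels is small, and — see §2.3 — kernels whose *integrated mass* is
dominated by the long-range term have a badly conditioned Fourier inverse.
Commissioned values must come from `fit_epid_kernel()`.

### Kernel fitting

For a flat square field of side `s`, the detector central value equals the
incident fluence times the fraction of the unit-sum kernel inside the
square, computed in closed polar form by `square_kernel_fraction()`
(64-node Gauss–Legendre; deterministic). The fit minimizes the spread of
(deconvolved EPID central value)/(chamber central dose) across field sizes
of 3–20 cm, both series normalized to the 10 cm field. Minimization is
cyclic coordinate descent with golden-section line searches over
`c ∈ [0,1]`, `μ_S ∈ [0.05, 5] /cm`, `μ_L ∈ [0.001, 0.5] /cm`, stopping when
a sweep improves the objective by less than 1e-8 or after 50 sweeps, with a
small multistart over `c`. The objective is the *standard deviation* of the
normalized ratios rather than the variance: both have the same minimizer,
but on the sd scale the prescribed 1e-8 stopping rule still resolves the
optimum (with the raw variance the descent stalls short of the 2% recovery
contract). Degenerate inputs in which EPID and chamber series are already
proportional drive the kernel to a delta (μ_S at its bracket cap); the
returned object then carries `boundary = TRUE`.

The bracket layout also removes the label-swap ambiguity
(`c ↔ 1−c`, `μ_S ↔ μ_L`): the long-range coefficient cannot exceed
0.5 /cm, the short-range cannot fall below 0.05 /cm.

### Deconvolution and regularization

Deconvolution is division in Fourier space on a grid zero-padded to twice
the image (the kernel is evaluated with wrapped distances on the padded
grid, so the padding covers its support). Two regularizations apply:

- **Spectral floor, as band truncation.** Frequencies where the kernel
  response falls below `1e-6` of its maximum are *unrecoverable*: any
  content there is amplified by at least a factor 1e6, so padding
  artifacts and pixel noise dominate the inverse. The implementation sets
  the inverse response to zero at those frequencies (with a warning) rather
  than clamping the divisor to the floor — clamping was tried first and
  destroyed clean-image round trips, because the crop/pad mismatch of any
  finite panel has broadband content. The cost of truncation is a
  band-limited reconstruction, negligible in the field interior for
  penumbra-smoothed fields.
- **Noise filter.** A unit-sum exponential kernel `exp(−d/range)`
  (default range 0.1 cm; 0 disables) is applied as a multiplicative
  low-pass *after* the division. Placement after the division is a design
  choice — pre- or post-division was not determinable from the method
  description; post-division makes the filter's effect independent of the
  kernel and keeps the division itself untouched for well-conditioned
  kernels.

*Conditioning caveat.* The two-exponential kernel's Fourier transform has
DC mass `(1−c)·2π/μ_S² + c·2π/μ_L²`. When the long-range term dominates
this sum (e.g. `c = 0.35, μ_L = 0.12 /cm`, putting >95% of the mass in the
tail), the normalized spectrum drops below the floor over most of the band
and deconvolution cannot recover the field. This is a property of the
physics (a detector that blurs away most information cannot be inverted),
not of the implementation; the fit brackets and defaults keep commissioned
kernels out of this regime.

### Acquisition corrections

- *Backscatter*: subtract `a · (P ⊗ G_σ)` restricted to the arm-side half
  of the panel (rows past the mid-line; `backscatter_support = "full"`
  available). One-sided support reflects the arm's position under the
  panel; amplitude and σ are user configuration because no printed values
  exist for them.
- *Panel displacement*: per-gantry-angle translation by the negated
  tabulated displacement, bilinear resampling, periodic linear
  interpolation between tabulated angles; displacement at 0° is (0,0) by
  definition of the reference image.
- *Horns*: multiplicative map `1/(1 + A(1 − exp(−r²/2σ²)))` at the
  isocenter plane. The functional form is a design choice (unstated in the
  source method); it is exactly invertible and leaves the axis untouched.
- *Projection*: coordinates scale by `SAD/SDD` (0.04 cm pitch at 140 cm →
  0.028571 cm at 100 cm), intensity by `(SDD/SAD)²`.

Correction state is tracked in `corrected` flags; double application is a
state error, and deconvolution refuses images without both flags.

## 3. Dose engine

### TERMA

One divergent ray per voxel center (matching the O(N³) cost of the
original engine; no sub-voxel supersampling), exact voxel-boundary
traversal for radiological depth, bilinear fluence lookup at the ray's
isocenter-plane crossing, inverse-square from the source, and per-bin
spectral attenuation (no beam-hardening shortcut: the per-bin sum *is* the
polyenergetic model; whether the original used hardening-corrected
effective attenuation was not determinable).

### Collapsed-cone transport with CCK tables

The point kernel is collapsed onto 36 zenith bands — 22 uniform sub-bands
over 0–44°, 1 over 44–50°, 9 over 50–95°, 1 over 95–120°, 3 over 120–180° —
crossed with 8 uniform azimuths: 288 directions. (The source text lists
these bands but states a total of 280; the explicit listing gives
22+1+9+1+3 = 36 × 8 = 288, and the construction follows the listing. The
discrepancy is recorded, not resolved.) Zenith samples sit at sub-band
midpoints; each direction carries the exact patch solid angle
`2π(cos θ₁ − cos θ₂)/8`.

Per band the tables hold the differential kernel `k_b(r)` (energy per unit
radiological length), its cumulative `K_b`, and the cumulative–cumulative
`C_b = ∫K_b`. Because the tabulated kernel is interpreted as a
piecewise-constant radial density, `K` (cumulative sums) and `C`
(trapezoid of a piecewise-linear function) are *exact*, not quadrature
approximations.

For a receiving voxel of radiological chord `h` along direction ω, a
marched source segment at radiological radii `[r₁, r₂]` with TERMA `T`
contributes

    ΔD = T · [ (C(r₂+h/2) − C(r₂−h/2)) − (C(r₁+h/2) − C(r₁−h/2)) ] / h / 8

— the CCK window average that realizes the "inherent voxel integration"
which makes the CCK discretization more accurate than plain cumulative
lookup. The self segment (the receiver's own TERMA, `r₁ = 0`) uses the
exact double integral over source and receiver positions within the voxel,
`ΔD = T·C(h)/h`. This last term matters: with the naive window formula the
per-ray deposition fails to telescope and a steep kernel loses its
sub-half-chord self-deposition (a ~20% energy deficit was measured during
development); with it, the per-ray sum telescopes exactly and the
engine-level energy-conservation test holds to better than 1e-4.

Kernels are evaluated at density-scaled (radiological) radii accumulated
along the ray — O'Connor scaling — and kernel axes stay aligned with the
beam axis (no divergence tilt), the standard collapsed-cone approximations.
Negative rounding residues of the C-differences are clamped at zero.

### The brute-force oracle

`point_kernel_superpose_oracle()` is the independent check: an exact double
sum over (interaction, receiving) voxel pairs using the same point kernel,
with straight-line radiological scaling. One refinement was needed for the
comparison to be meaningful: close to a point source the kernel density
varies by orders of magnitude across a voxel, and evaluating it at the
voxel *center* misrepresents the volumetric integral (the face neighbors of
the source subtend far more solid angle than a 2° zenith band). Pairs
closer than 2.5 voxel widths are therefore integrated over 5³ sub-voxel
points. The collapsed-cone result and the oracle then agree on a 21³
homogeneous grid to within 3% of the maximum dose (excluding the source
voxel itself, whose self-dose convention differs by construction), with a
mean discrepancy two orders smaller — computed in
`tests/testthat/test-acceptance.R`. The residual near-field difference is
inherent to collapsing cone energy onto discrete axes and concentrates in
the first shell of voxels around the source.

## 4. Gamma evaluation

Global normalization (`ΔD = dose criterion × max(D_ref)`), both grids
trilinearly resampled to 1 mm, low-dose threshold applied to the
*reference* grid — exclusions must not depend on the distribution under
test; which grid the original statistic used was not determinable. The
search scans spatial offsets on a 0.2 mm lattice sorted by distance, stops
as soon as the geometric term alone exceeds the current best (admissible:
the lattice minimum is exact), then refines around the best offset on a
0.1 mm sub-lattice. The refinement step is what lets the 0.2 mm search
match the 0.1 mm exhaustive oracle to within 0.01 with identical pass
rates on smooth fields with clinical-scale gradients (a few percent of
maximum per millimeter); without it the two lattices differ at the 0.02
level wherever the dose-difference term changes by O(1) between lattice
points. Gamma values are capped at `gamma_cap` (default 2), which also
bounds the search radius at `gamma_cap × dist_crit`.

A voxel passes at `γ ≤ 1` *inclusive* (the field convention; the source
table counts "smaller than 1" — boundary cases are measure-zero on real
data), with a 1e-9 guard because synthetic tests construct voxels exactly
on the boundary.

## 5. Synthetic fixtures: what a green test does and does not establish

The generators emulate the *inputs* of the chain, not a clinical machine:

- `make_slab_phantom()` reproduces the published material densities
  (adipose 0.920, muscle 1.040, bone 1.850, lung 0.250 g/cm³) and the 30 cm
  stack; the layer order and thicknesses of the preset
  (muscle 7.2 / bone 3.0 / muscle 5.4 / lung 9.0 / muscle 5.4 cm) are a
  plausible arrangement chosen here, commensurate with the 0.3 cm default
  grid — the published arrangement exists only graphically. Mass density is
  mapped to relative electron density by identity, a documented
  approximation (the two differ by a few percent per tissue); this is
  harmless for engine validation because engine and oracle share the grid.
- `make_square_fluence()` produces unit-height fields with error-function
  penumbras (50% level exactly at the field edge, any blur width).
- `simulate_epid_image()` inverts the fluence model exactly (projection,
  `1/c_ad`, kernel convolution) and optionally adds the backscatter ghost
  and seeded Gaussian noise. RNG state is restored after use.
- Spectra are literature-style 6/10 MV shapes; the point kernel is the
  analytic two-exponential `h(r,θ) = (A(θ)e^{−ar} + B(θ)e^{−br})/r²` with
  forward-peaked angular envelopes, tabulated in closed form.

Consequently a green suite establishes *transport correctness* (the engine
reproduces what its kernel and geometry imply, conserves energy, scales
with density, inverts its own forward models) — not *clinical accuracy*,
which requires commissioned kernels, measured spectra and machine data that
cannot ship with a package. The published clinical pass rates and dose
differences are therefore not reproduced here; the qualitative pattern
(3%/3 mm ≥ 2%/2 mm pass rates, water-override agreeing better than
original-material) is asserted as a property instead.

Engine-facing tests use a compact kernel (`a = 3, b = 0.8 /cm`, range
~10 cm) so that 21-voxel grids contain the kernel support — grid sizes and
the end-to-end slab plan are deliberately scaled down (6 cm lateral, 10 cm
stack, two fields) to keep the full suite within minutes on one CPU; the
algorithms themselves are resolution-independent.

## 6. Numerical choices (summary table)

| Quantity | Value | Where |
|---|---|---|
| Kernel spectral floor | 1e-6 of max, band truncated | `deconvolve_to_fluence()` |
| Noise filter | exponential, 0.1 cm, post-division | `correction_model()` |
| FFT padding | 2× image, wrapped kernel | `deconvolve_to_fluence()` |
| Fit stop | sweep improvement < 1e-8 or 50 sweeps | `fit_epid_kernel()` |
| Fit brackets | c [0,1]; μ_S [0.05,5]; μ_L [0.001,0.5] /cm | `fit_epid_kernel()` |
| CCK table | 0.1 cm step, 60 cm extent (defaults) | `build_cck_table()` |
| Cone set | 36 zenith bands × 8 azimuths | `build_cone_set()` |
| Dose grid default | 0.3 cm isotropic | `slab_spec()` |
| Gamma resampling | 1 mm trilinear | `gamma_3d()` |
| Gamma search | 0.2 mm shells + 0.1 mm refinement, cap 2 | `gamma_3d()` |
| Gamma oracle | 0.1 mm dense lattice, ≤ 25³ voxels | `gamma_bruteforce_oracle()` |
| Pass condition | γ ≤ 1 + 1e-9 (inclusive) | `gamma_3d()` |
| DVH bin width | 0.05 Gy | `compute_dvh()` |
| D_max | voxel point maximum (no volume smoothing) | `dose_difference_metrics()` |
| Attenuation lookup | log–log linear | `attenuation_lookup()` |

## 7. Known limitations

- No TIFF/DICOM portal-image import or RT Structure Set parsing; volumes
  travel as NRRD, masks as label arrays, images as matrices.
- No MU-based absolute dose chain: absolute scale is one scalar `c_ad`.
- Interface (charged-particle disequilibrium) accuracy is limited to what
  density-scaled water kernels provide; no electron contamination, no
  head-scatter source model.
- Couch and collimator rotations are unsupported (gantry only).
- The CCK self-voxel and near-field conventions make doses in the first
  voxel shell around strong TERMA gradients engine-specific at the
  few-percent-of-maximum level.
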
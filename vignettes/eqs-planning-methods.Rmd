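---
title: "Electro-quasistatic SAR and temperature planning for capacitive interstitial hyperthermia"
author: "ihtplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electro-quasistatic SAR and temperature planning for capacitive interstitial hyperthermia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dual-electrode capacitive applicators for interstitial hyperthermia are
thin rods (2 mm catheter) carrying two 20 mm electrodes 5 mm apart,
insulated from the tissue by a ~30 um Parylene C layer. Implanted in a
prostate in a brachytherapy-style lattice and driven at 27 MHz, they
deposit power capacitively in the surrounding tissue. Planning such a
treatment requires the specific absorption rate (SAR, W/kg) produced by
*each electrode* quickly enough for interactive optimization — but the
micrometre layers force sub-0.1 mm voxels, and full-wave solvers at
27 MHz are hopelessly slow for that purpose.

`ihtplan` implements the fast route: an electro-quasistatic (EQS)
voxel solver, an analytically equivalent simplified applicator geometry
that removes the thin layers, per-electrode field superposition, and the
validation machinery (3D gamma-index, SAR accuracy metrics) needed to
show that the fast model agrees with a detailed-geometry reference. A
Pennes bioheat solver maps SAR to temperature against the clinical
constraint set.

## Electro-quasistatic model

At 27 MHz the wavelength in tissue exceeds one metre — two orders above
the applicator scale — so the electric field derives from a complex
scalar potential:

$$\nabla \cdot \big[(\sigma + j\omega\varepsilon)\,\nabla V\big] = 0,$$

with constant-voltage (Dirichlet) electrodes, the domain boundary
grounded at 0 V at least 10 mm away from the volume of interest, and
$E = -\nabla V$, $\mathrm{SAR} = \sigma |E|^2 / (2\rho)$.

**Discretization.** Node potentials on a rectilinear non-uniform grid
with cell-centered materials. The conductance of the edge between two
adjacent nodes sums $\kappa \cdot (\text{quarter dual-face area}) /
(\text{edge length})$ over the up-to-four cells sharing the edge. Along
an axis, consecutive edges then combine in series, which makes the
scheme exact for 1D layered media (verified in the tests); on aligned
boundaries it is second-order accurate (measured orders 2.00/2.00 on a
harmonic Dirichlet problem). Curved electrode surfaces are rasterized,
so near-shell errors are geometry-limited at first order — the
concentric-cylinder validation therefore checks the analytic
$\ln(r)$ profile to 1% and $|E| \propto 1/r$ to 2% rather than a formal
convergence order on that case.

**Conductors.** Copper electrodes are perfect conductors: their cells
are excluded from the solve and every node touching them is a Dirichlet
node at the electrode voltage. Per-electrode input power is
$\tfrac12\mathrm{Re}(V_e I_e^*)$ with $I_e$ the total complex current
(conduction + displacement) leaving the electrode's node set; the sum
over electrodes balances the volume integral of $\sigma|E|^2/2$ to
within 2% on the benchmark grids (exactly, on layered test problems).

**Linear solver.** BiCGSTAB with an SSOR preconditioner on the 7-point
complex stencil, written in C++ for the multi-million-node detailed
grids. The relaxation factor defaults to 1.9 (measured roughly half the
iterations of 1.5 on both benchmark grid classes); the convergence
criterion is a relative residual of 1e-9, and results are deterministic.
The same kernel (real coefficients, extra diagonal term) drives the
implicit bioheat steps.

## Grids

The paper-style grid settings are the defaults: 0.02 mm transverse steps
across each applicator cross-section in the detailed geometry (0.1 mm
for the simplified one), geometric grading bounded by a factor 1.2 per
cell up to a 2 mm cap outside, a uniform 1 mm longitudinal step, and a
10 mm margin between the model extent and the grounded boundary. Node
coordinates are snapped to 1e-9 mm so mirrored applicator positions
produce exactly mirrored grids — without the snap, half-open shell
classification can rasterize two symmetric applicators differently when
shell boundaries land on cell centers.

## The simplified applicator and its equivalence math

The real applicator's electrode/dielectric pair is a coaxial capacitor;
its thin layers are what force fine voxeling. The simplification
replaces the cylindrical electrode by a square cuboid of equal lateral
surface (edge $= \pi d/4$, which preserves diameter *ratios* exactly)
and then thickens the shells to voxel-friendly sizes — electrode edges
1.0 to 1.4 mm, dielectric 1.4 to 1.8 mm — while preserving the layer
capacitance by scaling the dielectric permittivity:

$$\varepsilon' = \varepsilon\,
  \frac{\ln(\alpha_o'/\alpha_i')}{\ln(\alpha_o/\alpha_i)} .$$

With Parylene C ($\varepsilon_r = 2.4$) this gives
$\varepsilon_r' = 21.008$, and the preservation is an exact algebraic
identity (asserted to 1e-12 in the tests). The dielectric's conductivity
is kept at the Parylene value; it sits five orders below tissue
conductivity, so the choice is immaterial. A `match = "coaxial"` option
instead matches the cylindrical-layer capacitance value (a factor
$\pi/2$ on $\varepsilon'$); the default matches cuboid-to-cuboid,
following the order of the derivation above.

The simplified rod is classified by point-in-cuboid tests in the
applicator frame (any axis direction); the detailed cylindrical rod is
restricted to grid-parallel axes and rasterized by a supersampled
majority vote over each cell cross-section. The vote uses a 4x4
stratified pattern (offsets $\pm 1/8$, $\pm 3/8$ of the cell) rather
than 3x3: with 0.02 mm cells the 2.00/2.06 mm shell radii fall exactly
on 3x3 sample points, which biased the copper shell volume by -7%;
the stratified pattern keeps samples off the boundaries and measures
-2.2% at 0.02 mm, converging to +0.4% at 0.005 mm (the tests assert
the 5% band).

## Superposition

Because the problem is linear in the drive voltages, solving once per
electrode (13 V on that electrode, all others grounded) yields a field
basis $\{E_i\}$; any amplitude/polarity plan evaluates as
$E_\mathrm{tot} = \sum_i n_{A,i} n_{\phi,i} E_i$ without re-solving.
The basis also stores the electrode current matrix, so per-electrode
input powers of any plan — and the fixed-point rescaling to a power
target — cost a matrix-vector product. The tests assert the superposed
field equals a direct multi-electrode solve to 1e-8 in relative
max-norm (both routes solved to a 1e-12 residual).

## Benchmarks and validation protocol

Two programmatic phantoms reproduce the benchmark conditions at desk
scale:

* **Homogeneous**: parallel applicators on a 9 mm lattice in muscle.
  The full 18-applicator layout (5 columns x 4 rows minus the two
  upper-central positions, VOI 54 x 43 x 54 mm) is the default; the
  reduced phantom used by the automated comparisons has 2 applicators
  with the VOI padding scaled proportionally (one lattice spacing
  transversally, 4.5 mm axially).
* **Complex**: three tissues (fat/muscle/prostate) with a planar
  prostate-fat interface crossed by the applicators at z = 5 mm, a
  parallel interface with the first applicator centered on it, a muscle
  floor below z = -15 mm, and non-uniform spacings (7.5 / 10.5 mm in
  the reduced 3-applicator version; squeezed/stretched rows in the
  full one).

`benchmark_comparison()` runs the whole chain: simplified basis,
per-electrode normalization to 0.7 W, a detailed cylindrical-layer
reference solve normalized to the same 0.7 W per electrode (the two
geometries differ by ~35% in electrode admittance, so equal-power — the
standard benchmark condition — is what makes the comparison test the
field *distribution* rather than a global scale), resampling of both
SAR volumes onto a uniform 0.25 mm comparison grid over the VOI with
applicator interiors excluded, and gamma analysis at 1%/0.5 mm and
2%/2 mm.

**Gamma details.** For each reference voxel the generalized
$\Gamma = \sqrt{\Delta\mathrm{SAR}^2/DD^2 + \|\Delta r\|^2/DTA^2}$ is
minimized over evaluated samples within $3 \cdot DTA$ (beyond that,
$\gamma > 3$ already fails), visiting offsets in distance order with
early termination. The dose criterion normalizes to the global maximum
reference SAR in the VOI; a voxel passes at $\gamma \le 1$ (boundary
ties are measure-zero). The evaluated volume is sampled by trilinear
interpolation on a lattice whose step is the largest divisor of the
comparison step not exceeding $DTA/3$ — aligning the lattice with the
reference positions so identical volumes score exactly zero; an
interpolation-free mode evaluates on the volume's own samples and is
checked against an exhaustive brute-force oracle on small volumes.

## Bioheat

`solve_pennes()` integrates
$\rho c\,\partial T/\partial t = \nabla\cdot(k \nabla T)
- \rho_b c_b w_v (T - T_b) + \rho\,\mathrm{SAR}$
with implicit Euler (default 1 s steps; halving the step changes a
20-minute field by under 0.01 degC) on the same grid machinery.
Perfusion from the material table (mL/kg/min) converts as
$w_v = \mathrm{perfusion} \cdot \rho \cdot 10^{-6}/60\ \mathrm{s}^{-1}$.
Blood parameters default to 1050 kg/m^3, 3617 J/kg/K and 37 degC —
standard literature values, configurable. Boundaries are fixed at
baseline 37 degC by default (they sit 10 mm or more from the VOI); an
insulated option emulates an unbounded medium and makes the uniform
steady state $\Delta T = \rho\,\mathrm{SAR}/(\rho_b c_b w_v)$ exact,
which the tests use as the analytic oracle. Conductor cells conduct
with catheter (POM) thermal properties — the copper shell is tens of
micrometres and thermally negligible — and deposit no power.
`constraint_report()` checks region maxima against the clinical limits
(47 degC any tissue; urethra 43.5, bladder 42.5, rectum 41.5 degC).

## Problem sizes and numerical choices

The automated comparisons use the reduced phantoms: about 4.5 M cells
for the 2-applicator detailed reference, 6.5 M for the 3-applicator
complex one, 0.5-0.8 M for the simplified models, and a 0.25 mm
comparison grid (~1.7-2.8 M voxels); these sizes keep a full run in
minutes on one CPU while leaving the applicator geometry, grid steps,
drive power and agreement criteria at their full-scale values. Ties in
the rasterization vote resolve to the innermost layer; half-open
interval conventions ([lo, hi)) apply to VOI boxes and shell bands;
amplitude normalization stops when every electrode is within 1% of the
power target.

## What the phantoms do and do not show

The generators emulate the benchmark geometry: parallel applicators,
straight planar tissue interfaces, homogeneous material blocks. They do
not emulate patient anatomy — curved interfaces, oblique non-parallel
needles (the simplified rasterizer accepts them; the detailed reference
does not), CT-derived tissue maps, or thermoregulatory physiology.
Agreement on the phantoms therefore validates the *applicator model and
solver*, not segmentation or patient-specific workflow. Temperature
results additionally depend on perfusion values that vary strongly
between patients; the bioheat solver is validated against analytic
balances, not clinical thermometry.

## Reproducing the benchmark numbers

```{r}
library(ihtplan)
hom <- benchmark_comparison("homogeneous", n_applicators = 2)
hom$metrics
cpx <- benchmark_comparison("complex")
cpx$metrics
```

`scripts/acceptance.R` wraps exactly this and writes the passing rates
and accuracy to JSON.
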
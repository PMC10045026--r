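---
title: "Methods: image-based aortic hemodynamics with aortaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based aortic hemodynamics with aortaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaflow)
```

## Scope and model

`aortaflow` implements the desk-scale stages of a patient-specific CFD
workflow for aortic hemodynamics — the kind used to compare healthy
aortas with dissected ones (true lumen / false lumen anatomies). Blood is
treated as an incompressible Newtonian fluid with density
$\rho = 1060\ \mathrm{kg/m^3}$ and dynamic viscosity
$\mu = 3.71\times10^{-3}\ \mathrm{Pa\,s}$ inside rigid walls; the flow
regime is tracked through the inlet Reynolds number
$Re = u\rho D/\mu$. The 3D RANS solve itself is deliberately out of
scope: the package covers what surrounds it — geometry extraction from CT
slices, the boundary-condition mathematics, the wall-shear and vortex
post-processing, and the scalar statistics used to verify a simulation —
and validates every stage against closed forms on synthetic inputs.

## Segmentation chain

Lumen cross-sections are extracted per slice as: region-of-interest crop,
histogram equalization, optional adaptive threshold smoothing,
binarization, Moore-neighbor boundary tracing with Jacob's stopping
criterion, and assembly of the traced pixels into a 3D point cloud with
$x = (\mathrm{col}-1)\,s_{xy}$, $y = (\mathrm{row}-1)\,s_{xy}$,
$z = (\mathrm{slice}-1)\,s_z$ (indices 1-based, $s_{xy}$ the in-plane
pixel spacing in mm, $s_z$ the slice thickness).

Design choices where the procedure is underdetermined:

* **Equalization.** The classical CDF mapping
  $v \mapsto \mathrm{round}\!\big((F(v)-F_{min})/(N-F_{min})\cdot(2^b-1)\big)$,
  which is monotone and stretches the occupied range to the full bit
  depth; a constant image is returned unchanged.
* **Adaptive filter.** The local neighborhood is the 4-connected cross
  *including* the center pixel (a 5-pixel mean), with replicate padding at
  the frame edge; where that mean exceeds `mean_threshold` the pixel is
  decremented by `decrement`, clipping at zero. Defaults are 60% and 10%
  of the bit-depth maximum; both are configurable because no constants
  are prescribed by the procedure itself.
* **Threshold rule.** The default is automatic (Otsu), keeping the
  pipeline minimally supervised, with a fixed numeric override. One
  subtlety is deliberate: equalization *flattens* the histogram, which is
  exactly the structure Otsu needs. Since both equalization and
  thresholding are rank-based, the split is therefore estimated on the
  raw crop and transported through the monotone equalization map. When
  the adaptive filter is enabled, the transported threshold is lowered by
  `decrement` (the filter lowers the high-local-mean lumen interior by
  that constant); untouched background pixels that enter the widened band
  are scattered speckle and are removed by the small-component filter
  (components below 8 pixels are discarded, configurable).
* **Tracing.** Moore-neighbor tracing starts at the topmost-then-leftmost
  pixel of each 8-connected component, entered from its west neighbor,
  scanning the Moore neighborhood clockwise from the backtracked
  background pixel; it terminates when the initial (pixel, backtrack)
  state recurs, which is Jacob's criterion of re-entering the start from
  the original direction. On simply connected masks the traced set equals
  the brute-force boundary definition (foreground pixels with a
  4-connected background neighbor) — the suite asserts this equivalence;
  interior holes are not traced (lumens are simply connected).

Consequences: the pipeline is deterministic, and invariant under any
strictly increasing same-depth intensity map (rank preservation); across
bit depths the invariance holds only up to equalization quantization
ties.

## Inlet and outlet boundary models

**Inlet waveform.** A sampled aortic-root velocity waveform is
interpolated by least-squares trigonometric regression at multiples of
$1/T$ ($T = 0.96$ s); on a uniform grid this reproduces the FFT result,
and it remains well-posed for non-uniform sampling. The fit reports
$R^2 = 1 - SS_{res}/SS_{tot}$; eight modes reproduce a physiologic
waveform essentially exactly (the suite checks $R^2 = 1$ to machine
precision on any noiseless 8-harmonic input).

**Windkessel outflow.** Each outlet pressure follows the 3-element
(RCR) Windkessel. The printed compact form of this ODE is dimensionally
inconsistent as typeset, so the package implements the standard circuit
in the distal-pressure state $p_2 = p - R_1 Q$:
$$\frac{dp_2}{dt} = \frac{Q}{C} - \frac{p_2}{R_2 C}, \qquad
  p = p_2 + R_1 Q,$$
whose steady state is $p = (R_1+R_2)Q$ — the physics the cited model
describes. Integration is explicit Euler as stated, default
$\Delta t = T/1000$; steps at or beyond the stability bound $2R_2C$ are
rejected, and passivity (non-negative pressure under non-negative flow
from rest) additionally requires $\Delta t \le R_2C$. `p_initial`
initializes the ODE state $p_2$, so a zero-flow run decays exactly as
$p_{2,0}\,e^{-t/R_2C}$.

**Parameter estimation.** Without per-patient constants to reproduce,
`wk3_estimate()` uses the standard split: total resistance
$R_T = \bar p_{target}/\bar Q$, proximal fraction $R_1 = f_1 R_T$
(default $f_1 = 0.1$), $R_2 = R_T - R_1$, and compliance from a
prescribed time constant $R_2C = f_\tau T$ (default $f_\tau = 0.35$,
a typical arterial decay fraction of the cycle). The
estimate→simulate round trip reproduces the target mean pressure within
the Euler discretization error.

**Turbulence initialization.** From rest, $k = \tfrac12 u_{0,max}^2$,
$\epsilon = C_\mu^{3/4}k^{3/2}/L$ with $L = 0.038D$ and $C_\mu = 0.09$.
Two printed-form issues are resolved deliberately: the turbulent
viscosity is returned kinematic, $\nu_t = C_\mu k^2/\epsilon$ (the
quantity the $k$–$\epsilon$ model transports; the printed extra $\rho$
factor would make it dynamic — available via `dynamic = TRUE`), and
$k = \tfrac12 u_{max}^2$ is implemented as printed even though it implies
a ~58% turbulence intensity at peak; if an intensity factor was intended
upstream, it was not recoverable from the source material.

## Wall shear and vortex indices

* **WSS** is the wall traction $-\mu\,\partial\vec u/\partial\hat n$
  evaluated with a one-sided first-order difference between the no-slip
  wall and a paired near-wall sample at distance $d$ (mirroring a
  first-cell-center evaluation in a low-Reynolds wall treatment without
  wall functions). The full vector is reported by default; a flag
  removes the wall-normal component. Convergence in $d$ is first order
  by construction, asserted in the suite.
* **WSF** is the discrete surface integral $\sum_f \vec{WSS}_f A_f$.
* **TAWSS / OSI** use the periodic trapezoidal rule on a uniform
  one-period grid $t_l = (l-1)T/n$ — on that grid it reduces to the
  sample mean, is spectrally accurate for periodic integrands, and both
  integrals of OSI use the same rule. OSI is clipped to $[0, 0.5]$
  against round-off; a face with identically zero history is a 0/0 case
  and returns 0 with a warning (a dead face does not oscillate).
* **Q-criterion** uses the standard subtraction form
  $Q = \tfrac12(\|\Omega\|_F^2 - \|S\|_F^2)$. The printed equation lacks
  the sign between the norms, but only the subtraction form is
  consistent with its own usage (vortexes where $Q>0$, $Q<0$ regions
  discarded as not significant). Connected $Q>0$ regions are labeled
  with 6-connectivity on the lattice (face neighbors — the conservative
  choice; the source does not state its connectivity or threshold).
* **Turbulence intensity** $T = \sqrt{2k/3}/|u|$ is undefined at
  stagnation points; those samples return `NA` and are excluded from
  thresholded statistics.
* **y+** uses $u_\tau = \sqrt{WSS/\rho}$, $y^+ = y\,u_\tau/\nu$.

Velocity gradients are computed either exactly (analytic fields) or by
central differences on a regular lattice with one-sided first-order
stencils at the boundary; unstructured point sets are rejected rather
than silently reconstructed, because solver-grade gradient
reconstruction is out of scope.

## Verification statistics

The cycle-convergence error averages the relative cycle-to-cycle
pressure change over the $N_s$ samples of a cycle; the summand is taken
in absolute value, since a signed mean could cancel oscillating
transients and defeat its purpose as a convergence criterion. The WSF
mesh-sensitivity metric normalizes the mean absolute difference between
two grids by the dynamic range of the *reference* (first) series; the
source leaves the normalizing grid unstated, so the convention here is
explicit and the metric is mildly asymmetric — pass the finer grid
first. Flow distributions are percentage shares of the inlet cycle
volume; relative perfusion changes use the reduction-positive convention
$100(1 - s_i/s_i^{base})$ and are additionally rounded
half-away-from-zero to integers for reporting (a handful of published
roundings differ from strict table arithmetic by one unit; the package
asserts the arithmetic). Pressure drops convert at 133.322 Pa/mmHg.

## The synthetic world

The generators produce every input the pipeline consumes, under stated
physiologic conditions:

* **CT phantoms**: ellipse-section lumens with per-slice center drift
  (emulating vessel curvature) over a uniform background, with additive
  Gaussian noise clipped to the bit-depth range. Defaults follow typical
  acquisition metadata (512-like frames scaled down, ~0.98 mm pixels,
  1.5 mm slices, 8–16 bit). The ground truth (interior masks, boundary
  pixels) is exact by construction. What this does *not* emulate: CT
  physics (beam hardening, Hounsfield calibration), partial-volume
  blur, anatomy other than convex lumens — so a green segmentation test
  establishes correctness of the algorithmic chain, not clinical
  robustness.
* **Analytic flow fields**: steady Poiseuille pipe flow
  ($u_z = 2\bar u(1-r^2/R^2)$, wall shear $4\mu\bar u/R$), Womersley
  pulsatile flow per harmonic of the driving pressure gradient (Bessel
  functions of complex argument; power series up to $|z| = 14$, 3-term
  Hankel asymptotics beyond, accurate to ~$10^{-6}$ across the aortic
  Womersley-number range), rigid rotation and pure shear for the vortex
  operators. Each field carries closed-form velocity, velocity-gradient
  and wall-shear callbacks — the oracles for the post-processing suite.
* **Inlet waveform**: a smooth raised-cosine template (systolic pulse at
  phase 0.16, early-diastolic backflow notch at 0.45) rescaled in closed
  form so the sampled peak (0.5 m/s), cycle mean (0.104 m/s ≈ 6 L/min
  through a 3.5 cm inlet) and backflow depth are met exactly; only these
  printed summary constraints are enforced, because the underlying
  sample values exist only graphically in the source material.
* **Outlet flows**: constant and half-sine systolic pulse shapes with
  known integrals.

All generators take an integer seed (default 0), save and restore the
caller's RNG state, and are bit-reproducible.

## Numerical choices and edge cases

* Periodic quadrature grids carry $n$ samples on $[0, T)$ without the
  duplicated endpoint; constructors reject non-uniform grids.
* Explicit Euler stability and positivity bounds are enforced/documented
  rather than silently damped.
* OSI 0/0 faces → 0 with a warning; turbulence intensity at $u = 0$ →
  `NA` with a warning; negative outlet cycle volumes (net backflow) are
  accepted with a warning.
* Components smaller than 8 pixels are discarded before tracing (noise
  suppression; configurable).
* Rounding for reported percentage changes is half-away-from-zero;
  unrounded values are always retained.

## Known limitations

No 3D RANS solve, hence no patient-specific pressure-drop or field-plot
reproduction; no surface fitting / SubD remeshing downstream of the
point cloud; no true/false lumen labeling; no non-Newtonian rheology or
fluid–structure interaction; WSS from arbitrary unstructured volumetric
solutions is out of scope by design.

## A worked example

```{r example}
# phantom -> point cloud
ph <- gen_phantom_ct(phantom_spec(noise_sd = 5, seed = 1))
seg <- segment_pipeline(ph$stack, adaptive = TRUE)
dice_coefficient(seg$masks, ph$truth_masks)

# inlet waveform -> 8-mode harmonic fit
wf <- gen_inlet_waveform()
fit_fourier(wf, n_modes = 8)

# outlet: estimate a Windkessel for 90 mmHg and verify the round trip
qs <- gen_outlet_flow("half_sine", amplitude = 3e-4)
wk <- wk3_estimate(mmhg_to_pa(90), qs)
run <- wk3_integrate(wk, qs, n_cycles = 8)
pa_to_mmhg(mean(run$p[run$times >= 7 * run$period]))

# wall shear indices on the analytic oracle field
fld <- gen_analytic_field(analytic_field_spec("poiseuille"))
wss <- compute_wss(fld$snapshots[[1]], fld$patch)
summary(sqrt(rowSums(wss^2)))  # ~0.212 Pa = 4 mu u_mean / R
```
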
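---
title: "Light dosimetry and treatment planning for interstitial photodynamic therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light dosimetry and treatment planning for interstitial photodynamic therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdtplan)
```

## The planning problem

Interstitial photodynamic therapy (I-PDT) treats deep-seated tumors — here,
malignant central airway obstructions — by inserting cylindrical diffuser
fibers (CDFs) through the bronchus directly into the tumor and illuminating
with 630 nm laser light after systemic photosensitizer administration.
Response correlates not with fluence alone but with a *rate-based* dose: a
point of the tumor counts as effectively dosed when it receives an
irradiance of at least 8.6 mW/cm² *and* a fluence of at least 45 J/cm².
Safety constrains the same plan from the other side: major blood vessels
adjacent to the tumor must stay below 8.6 mW/cm² and 9.5 J/cm² total.

A treatment plan therefore fixes, per fiber, an intensity (mW per cm of
diffuser, between 80 and 400 mW/cm, deliverable in 20 mW power steps) and an
illumination time, given fiber positions chosen by the clinician. This
package implements the computational chain behind such plans: light
propagation by the finite-element method, dose-volume metrics, and the
domination sub-maps power optimizer, plus the synthetic scenes and agreement
statistics needed to verify all of it.

## Light propagation model

Light transport in strongly scattering tissue is modelled by the optical
diffusion equation for the fluence rate $\phi(r,t)$ (the field the planning
literature calls "irradiance", mW/cm²):

$$\frac{1}{c_n}\frac{\partial \phi}{\partial t}
  - \nabla\cdot(\alpha_n \nabla \phi)\,/\,c_n = -\mu_a \phi,
  \qquad \alpha_n = c_n D_n,\quad D_n = \frac{1}{3(\mu_a + \mu_s')} ,$$

with, per tissue region $n$: absorption $\mu_a$ (1/cm), reduced scattering
$\mu_s' = (1-g)\mu_s$ (1/cm), and the speed of light in tissue
$c_n = c_0/n_{\mathrm{refr}}$. Boundary conditions:

* **Diffuser source** — the emitting band of each fiber is a Dirichlet
  surface held at $P_{\mathrm{laser}}$;
* **Outer boundary** — the Robin condition
  $c_n\phi + \alpha_n \nabla\phi\cdot \mathbf n = 0$, i.e.
  $\phi + D\,\partial\phi/\partial n = 0$ after the uniform $c_n$ cancels;
* **Initial condition** — a uniform background irradiance (daylight),
  relevant only to the transient mode.

The weak form is discretized with linear (P1) elements on tetrahedral
meshes; the transient mode uses unconditionally stable implicit (backward)
Euler steps. Because light equilibrates on the absorption time scale
$1/(c_n\mu_a)$ — a fraction of a nanosecond for these tissues — planning
uses the steady solver; the transient solver exists for verification (its
fixed point is exactly the steady solution, which the test suite checks).

Written as printed above, the steady operator carries a common factor $c_n$,
so the steady solution is invariant to a uniform refractive-index rescale;
with heterogeneous indices (tissue 1.37, blood 1.33) the per-region weights
matter and are assembled per element.

### The source irradiance conversion

Clinical prescriptions are in mW per cm of diffuser. The Dirichlet surface
value is derived by conserving the prescribed output power over the full
diffuser surface (lateral plus both end caps):

$$P_{\mathrm{laser}} = \frac{I\,L}{\pi d L + 2\pi (d/2)^2}.$$

For the reference phantom fiber (2 cm × 0.98 mm at 100 mW/cm) this gives
317.0 mW/cm². The diffuser diameter is not part of the clinical
prescription; 0.098 cm, a typical clinical diffuser, is the default and is
echoed in every report because the near field scales with it.

### Meshes

No general-purpose tetrahedral mesh generator is available to this package,
and none is needed for its scenes; both generators build structured,
deterministic grids subdivided into conforming tetrahedra with the
Freudenthal (Kuhn) 6-tet pattern:

* **Phantom scenes** use a cylindrical-shell grid around the fiber, graded
  geometrically from `target_h/2` at the diffuser surface (default: half the
  diffuser radius), held fine through the detector zone, coarsening toward
  the boundary; the outermost shell is morphed onto the cube faces so the
  outer boundary is exactly the block. The angular resolution is kept a
  multiple of 8 so the polygonal cross-section hits the square's corners and
  region volumes are exact. The fiber track is a through cavity: the
  emitting band carries the Dirichlet tag, the inert shaft above and below
  it receives the natural (no-flux) condition, and end-cap emission enters
  through the power normalization above rather than through meshed cap
  facets. The default `target_h` yields ~240 000 tetrahedra for the 10 cm
  phantom.
* **Airway scenes** (synthetic stand-ins for segmented patient anatomy) tag
  a uniform box grid by analytic shapes — ellipsoidal tumor, cylindrical
  vessels (critical structures), a bronchus carved out as a cavity — by
  element centroid. Fibers there are *embedded* Dirichlet node sources: a
  multi-centimetre scene cannot resolve a 1 mm cavity, so the nodes within
  `max(d/2, 0.75·target_h)` of the diffuser segment are constrained
  instead. This changes the absolute near field with mesh size, but every
  property the optimizer relies on — linearity, superposition, domination,
  safety audits — is exact regardless, which is what the airway scenes are
  for.

Mesh generation is fully deterministic: identical parameters give identical
meshes, and identical configurations reproduce byte-identical plans.

### Numerical choices

* Dirichlet conditions are imposed by row elimination with exact boundary
  values; the reduced system is symmetric positive definite and solved by
  sparse Cholesky factorization (residual checked against 1e-10 relative).
  One factorization serves all fibers of a scene.
* When several fibers exist, *all* source surfaces are constrained in every
  solve, inactive ones at zero. Single-fiber solutions then superpose
  exactly, which is what lets the optimizer rescale fields linearly and
  never re-solve the PDE.
* Coarse graded P1 meshes violate the discrete maximum principle mildly:
  the solution can dip a fraction of a percent below zero in the far field.
  Such undershoots are clamped to zero (an undershoot beyond 2% of the
  source value is treated as a broken mesh and raises an error instead).
  Linearity and superposition are verified on the unclamped solutions.
* Probing is barycentric P1 interpolation inside the containing
  tetrahedron, with containment located through the elements incident to
  the nearest mesh nodes.
* Convergence is assessed by `meshConvergenceStudy()`: successive
  refinements are flagged converged when probed values change by less
  than 2%.

### Verification against a closed form

In a homogeneous medium an infinitely long cylindrical Dirichlet source has
the exact solution
$\phi(\rho) = P_{\mathrm{laser}} K_0(\mu_{\mathrm{eff}}\rho)/K_0(\mu_{\mathrm{eff}} a)$
with $\mu_{\mathrm{eff}} = \sqrt{3\mu_a(\mu_a+\mu_s')}$. A quasi-2D scene (a
diffuser spanning the whole block) reproduces this at the mid-plane; the
test suite requires agreement within 5% at 2–10 diameters on the finest
study mesh (observed: ~6.9% → ~3.7% → ~1.4% under refinement), and the
discrete flux balance (source inflow = absorption + boundary outflow) closes
to well under 2% on converged meshes.

## Dose metrics

Fibers illuminate **one at a time** (sequential illumination through a
single bronchoscope channel), so:

* the irradiance criterion is applied per fiber, and the dose-rate volume
  histogram (DRVH) value is the tumor volume fraction whose *per-fiber
  maximum* irradiance reaches 8.6 mW/cm²;
* total fluence is $F(r) = \sum_k \phi_k(r) T_k$ (mW·s/cm² converted to
  J/cm² exactly once);
* the *effective* fluence counts each illumination only where its own
  irradiance meets the threshold,
  $F_{\mathrm{eff}}(r) = \sum_k \phi_k(r) T_k [\phi_k(r) \ge 8.6]$, and the
  effective rate-based dose DVH value is the tumor fraction with
  $F_{\mathrm{eff}} \ge 45$ J/cm².

An alternative reading — total fluence evaluated where the combined
irradiance passes the threshold — is available via the `effective`
argument of `doseReport()`, and a `simultaneous` combination mode exists
for completeness; neither is the default. Volume fractions classify each
tetrahedron by the mean of its four nodal values, weighted by element
volume: deterministic and mesh-consistent, with no sub-element
interpolation. Threshold comparisons are inclusive (`>=`). By construction
the effective-dose DVH never exceeds the DRVH.

## The domination sub-maps optimizer

Given per-fiber fields solved once at a common reference intensity, the
optimizer never touches the PDE again:

1. **Domination sub-maps.** Over the tumor and critical structures, each
   node is attributed to the fiber whose irradiance *strictly* exceeds all
   others there; exact ties belong to no fiber (a config flag assigns them
   to the lowest fiber id instead — with floating-point fields ties
   essentially never occur on real scenes, so the choice is inert in
   practice).
2. **Threshold Under-Dose factors.** Per fiber, the ratio of the 8.6 mW/cm²
   limit to the maximum of its sub-map over the critical structures — the
   safe linear scale factor for its intensity. A fiber dominating nowhere on
   the critical structures gets an infinite factor, resolved by the 400
   mW/cm intensity cap before any arithmetic uses it.
3. **Irradiance-safe scaling** applies the factors, re-checks the per-fiber
   critical-structure maxima, and iterates (default cap of 10 rounds); if
   the loop fails to validate, the still-offending fibers are scaled
   directly by `8.6 / (own maximum)`, which terminates unconditionally.
4. **Fluence-safe scaling** caps the total critical-structure fluence at
   9.5 J/cm² by scaling down the fibers identified through fluence
   domination sub-maps ($F_k = \phi_k T_k$); ties fall back to all
   contributors at the violating node, and a global proportional rescale
   guarantees termination. Scaling down cannot break irradiance safety.
5. **Quantization.** Powers are capped at `400 mW/cm × length`, then rounded
   *down* to the 20 mW laser calibration grid — never up, the safe
   direction.
6. **Treatment times.** The safe surface fluence accrued at the
   pre-quantization intensity is preserved: $t_k = F_k A_k / P_k$ with
   $A_k$ the diffuser surface area and $P_k$ the quantized power in W. This
   is the dimensionally consistent reading of dividing safe energies by
   safe powers; it leaves every critical-structure fluence unchanged while
   the reduced power keeps the irradiance safe.
7. **Final validation** recomputes both critical-structure maxima from the
   final fields; a violating plan raises an error rather than being
   returned.

Initial intensities default to 80 mW/cm (the clinical sweep floor) and the
initial time to 500 s, a typical per-fiber illumination; both are
arguments. `parametricSweep()` reproduces the manual planning step: 17
intensity levels from 80 to 400 mW/cm in steps of 20, each reporting
critical-structure exposure and tumor DRVH from one rescaled field.

## Agreement statistics

`ccc()` implements Lin's concordance correlation coefficient with
population (divide-by-n) moments,
$\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$, and `cccCI()`
the original asymptotic confidence interval through Fisher's
z-transformation (not a bootstrap; the choice is recorded in the result
object). With the five-point phantom series the exact CI method visibly
moves the digits, so only point estimates are treated as hard
reproductions; the interval is checked loosely.

## The phantom benchmark and what it shows

The validation scene reproduces a published solid-phantom dosimetry
experiment: $\mu_a = 0.224$/cm, $\mu_s' = 4.99$/cm, a 2 cm diffuser at
100 mW/cm, isotropic detectors at 5–25 mm from the fiber axis in the
mid-plane. The package's converged steady solution gives
(≈ 56.6, 15.4, 4.6, 1.5, 0.48) mW/cm² at the five distances, with CCC 0.974
against the measured means — above the benchmark's own lower confidence
bound of 0.953.

One caveat is worth stating precisely. At 15–25 mm the package agrees with
the benchmark's reference solver values (4.4, 1.5, 0.5) within a few
percent. At 5 mm the package computes ~56.6 where the reference solver
reported 47.0. An independent high-resolution axisymmetric finite-volume
solution of the same boundary-value problem — itself validated against the
$K_0$ closed form to better than 0.1% — puts the converged value at 55.3,
within 2.5% of this package's FEM. The 5 mm discrepancy is a *shape*
difference confined to the near field, which no admissible rescaling of the
source (diameter or power normalization) can remove without breaking the
far field; it is consistent with near-source discretization in the
reference computation, whose mesh parameters were calibrated against the
measurements and are not public. The package therefore reports its
converged value rather than tuning toward the printed one.

## What the synthetic scenes do and do not emulate

The airway generator produces the *structure* of the clinical problem —
a tumor with adjacent vessel-like critical structures and a bronchus, with
clinically constrained fiber placements (30–40° insertion, ≤ 4 cm depth,
≥ 6 mm vessel clearance, all checked by `checkPlacementConstraints()`) —
not patient anatomy: shapes are analytic, tissues homogeneous per region,
optical properties constant during illumination (photobleaching and
photochemistry are out of scope, as is any heat transfer or Monte Carlo
transport). Passing the optimizer's property suite on these scenes
demonstrates the method's guarantees (safety audits, quantization, strict
domination, determinism); it does not certify dosimetric accuracy in real
anatomy, which depends on segmentation and optical-property fidelity that
synthetic scenes cannot represent.

## Known limitations

* The Robin outer boundary is applied exactly as the model states, without
  an internal-reflection (refractive-index mismatch) factor; boundaries sit
  far from every quantity of interest in the bundled scenes, so the choice
  is inert there, but it matters if boundaries approach the tumor.
* Embedded-node sources in airway scenes make absolute near-field values
  mesh-dependent (see above); phantom-style meshed cavities should be used
  where absolute accuracy near the fiber is the point.
* The optimizer adjusts powers and times for *fixed* fiber positions;
  position search remains manual by design.
* P1 elements with aggressive grading undershoot slightly below zero in
  the far field; values are clamped and the behavior is bounded by an
  explicit error guard.

## Problem sizes used by the tests

The test suite solves the full 10 cm phantom (~240k tetrahedra) once, the
quasi-2D oracle comparison at three refinement levels (up to ~200k
tetrahedra), and exercises everything else on small structured scenes
(10³–10⁵ elements), which keeps the complete suite around a minute while
still covering the production problem size.
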
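---
title: "Modelling sacroiliac joint mechanics with pre-tensioned ligament springs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sacroiliac joint mechanics with pre-tensioned ligament springs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sijfem)
```

## The model

The sacroiliac joint (SIJ) transmits the load of the upper body from the
sacrum into the two ilia and onward to the legs. It moves very little —
fractions of a millimetre to a few millimetres — because it is clamped by a
dense ligament apparatus (interosseous, anterior and posterior sacroiliac,
sacrotuberous, sacrospinous and long posterior ligaments, plus the pubic
symphysis anteriorly) and stabilized further by the gluteal musculature.
`sijfem` is a self-contained quasi-static finite-element simulator of this
system on *synthetic* parametric pelvis geometry, built to study how joint
surface stress and relative joint motion respond to ligament pre-tension,
ligament stiffness and load intensity.

The mechanical model has four ingredients:

1. **Bone** — linear-elastic 4-node tetrahedra (constant strain). Each
   element receives an apparent density $\rho$ (g/cm³) from a synthetic
   cortical-shell/trabecular-core field, mapped to a Young's modulus by the
   empirical power law $E = 6.950\,\rho^{1.49}$ (GPa), and the modulus field
   is discretized into 40 equal-width material classes (bin midpoints as
   representatives). Poisson's ratio is a single global value, 0.3 by
   default — the mapping literature leaves it unspecified and 0.3 is the
   conventional choice for bone at this scale. Internally everything runs in
   a mm/N/MPa unit system.
2. **Ligaments and muscles** — tension-only spring fibers between
   attachment landmarks. Group stiffnesses follow the standard literature
   values (ISL 2800, ST 1500, SS 1400, LPSL 1000, PS $2\times500$, ASL 700,
   PSL 400 N/mm; gluteus maximus 344, gluteus medius 779 N/mm). Broad
   ligaments (ISL, ASL, PSL) are split into 3 fibers, distributing load over
   the attachment area while preserving the group total. Pre-tension of
   118 N per ligament group is imposed by shortening each fiber's stress-free
   reference length: $L_{\mathrm{ref}} = L_{\mathrm{inst}} - F_{\mathrm{pre}}/k$,
   i.e. a shortening to roughly 99.92% of the installed length for the
   sacrotuberous ligament geometry. Muscles are passive springs without
   pre-tension by default (both are configurable). Fiber directions update
   with deformation; an optional linearized mode (fixed directions,
   bilateral response) exists for verification problems that require an
   exactly linear system.
3. **Joint contact** — softened normal contact between the paired auricular
   surfaces and at the pubic symphysis. The pressure–overclosure relation is
   anchored at the cartilage: zero pressure at a clearance equal to the
   cartilage thickness ($c_0$ = 3 mm at the SIJ, 4 mm at the symphysis) and
   a pressure equal to the cartilage modulus ($p_0$ = 54 MPa and 5 MPa) at
   zero clearance. Between the anchors the default law grows exponentially,
   $p(g) = p_0\,(e^{(c_0-g)/c_0}-1)/(e-1)$; a linear law through the same
   anchors is available for comparison. Tangentially, Coulomb friction with
   $\mu = 0.4$ is regularized by a stick stiffness $k_t$ (100 MPa/mm).
4. **Loads and boundary conditions** — the sacrum is held fixed over the
   whole lumbosacral surface; gluteal ground points are fixed in space. Hip
   loads act at per-side hip-center points and are distributed evenly over
   the surrounding acetabular node set. Eight generic scenarios apply the
   extreme gait-load components ($F_x$ = 600, $F_y$ = 1200, $F_z$ = 2400 N)
   uniaxially or combined, unilaterally or bilaterally symmetric; five
   quasi-static gait phases (IHS, CTO, swing, CHS, ITO) are read off a
   synthetic hip-force curve whose per-component peaks equal those same
   extremes.

### What the synthetic geometry is (and is not)

Real studies of this joint segment patient CT scans. No such data ships
here; instead `build_pelvis_mesh()` constructs an idealized surrogate:
block-like sacrum and ilia on structured grids split into tetrahedra, with
near-vertical auricular plates whose inclination and curvature are the two
morphology parameters that distinguish the `female_like` and `male_like`
variants (6°/0.25 vs 12°/0.6; the male-like joint is more inclined and more
curved, consistent with the reported tendency of male auricular surfaces to
be more irregular). The left half is an exact mirror of the right half, the
auricular pairs start separated by a 2 mm gap (inside the 3 mm contact
engagement range) and the pubic faces by 3 mm. Landmarks for every ligament
fiber and muscle are snapped to mesh nodes at anatomically plausible
positions.

Because the geometry is a surrogate, absolute stresses and motions are not
anatomical predictions. What the model *is* built to reproduce are the
structural relationships: which inputs the outputs are sensitive to, with
which signs, and the qualitative contrast between the two morphology
variants. Passing tests therefore validate the machinery (element
formulation, contact and spring laws, pre-tensioning, sensitivity
computation) and the directions of effects — not patient-specific values.

The synthetic density field mimics a CT-derived map only coarsely: elements
touching the exterior surface form a stiff cortical shell
($\rho \approx 2.0$ g/cm³), interior elements a soft trabecular core
($\rho \approx 0.9$ g/cm³), with seeded Gaussian noise (sd 0.05 g/cm³) and
clamps chosen so the mapped moduli stay inside the 4315–22608 MPa band of
the reference material mapping. Real bone has continuous gradients,
anisotropy and spatially correlated intensity; none of that is represented.
The noise field is deliberately *not* mirror-symmetric — real density maps
are not — so symmetry checks use the noise-free two-level field
(`noise_sd = 0`).

## Solving the coupled problem

Each load case is solved by continuation. A single parameter first ramps the
ligament pre-tension *and* the contact engagement together from zero to
full — this makes the undeformed mesh an exact equilibrium at the start,
since at the initial 2 mm gap the exponential law already exerts pressure —
and then ramps the external load in five equal increments. Every
continuation step is solved by Newton iteration with a backtracking line
search; the residual tolerance is
$10^{-6}\,(\lVert F_{\mathrm{ext}}\rVert + 1\,\mathrm{N})$. A step that
fails to converge is halved automatically (down to 1/32 of the base
increment), and when the Newton direction fails to descend — the residual is
continuous but only piecewise smooth — the solver falls back to
Levenberg-regularized directions.

Two numerical choices matter for robustness and are worth stating:

* **Small-sliding contact.** Each follower node is paired once, in the
  reference configuration, with its closest target triangle (deterministic
  closest-point projection with lowest-index tie-breaking, exposed as
  `detect_gaps()`); the barycentric weights stay fixed during the solve
  while the contact normal follows the deformed triangle. Joint motions
  (≤ a few mm) are small against the facet size, so re-pairing during the
  solve would change results negligibly, and the frozen pairing makes the
  gap function smooth in the displacements — finite-sliding re-projection
  produces derivative kinks whenever a projection crosses a facet edge,
  which defeats Newton's convergence. The contact tangent is computed per
  node by finite differences of the local 12-dof force kernel, so normal
  rotation is captured consistently.
* **Smooth Coulomb saturation.** Inside the solver the friction traction is
  $t = -\mu p\, s/\sqrt{|s|^2 + s_0^2}$ with $s_0 = \mu p / k_t$: the same
  anchors as the sharp law $\min(k_t|s|, \mu p)$ (stick slope $k_t$ at zero
  slip, Coulomb limit $\mu p$ at large slip) but continuously
  differentiable. The sharp cap's elastic-slip scale
  ($\mu p / k_t \approx 0.008$ mm) sits three orders of magnitude below the
  joint motions, which made the sharp law effectively non-smooth at the
  solver's step sizes. `friction_traction()` exposes the sharp law itself.

Other conventions: 1-based node/element indexing (the R convention used by
every container in the language); the exported tie-break and sign
conventions for gaps (positive = separation); the pubic symphysis contact
runs as a balanced two-pass pair (half-weight passes in both directions)
so that a mirror-symmetric state produces mirror-symmetric forces, which a
one-sided node-to-surface pass cannot; and the symphysis is stabilized by
both its springs and its contact pair simultaneously, each individually
switchable.

## Outputs

* `surface_stress_summary()` — mean ± sd, median and 99th percentile of the
  element von Mises stress over the elements owning a surface patch
  (unweighted by default; percentiles interpolate linearly between order
  statistics).
* `joint_kinematics()` — relative SIJ translation (mm) and rotation (deg)
  from least-squares rigid fits of the two patch displacement fields. The
  relative transform is the ilium fit composed with the inverse sacrum fit;
  translation is evaluated at the joint-gap centroid, which makes the
  metric independent of the coordinate origin, and rotation is reported as
  the total rotation angle. This metric is exactly rigid-motion invariant
  but only asymptotically linear in the displacements, which is why the
  linear-limit identity (translation sensitivity to load intensity = 1) is
  verified at small loads.

## Sensitivity analysis

`sweep_parameter()` re-solves the model one-at-a-time over factors of an
input; `sensitivity()` reports
$s = \Delta(\text{output}/\text{output}_{\text{baseline}})/\Delta(\text{factor})$
as the least-squares slope over the sweep (for symmetric three-point sweeps
this equals the central difference exactly). The standard study sweeps
ligament reference length over 0.998–1 (less shortening = less
pre-tension), ligament stiffness over 0.6–1.4 and load intensity (body
weight) over 0.6–1.4, three points each. A negative $s$ means the output
falls as the input grows. On the synthetic geometry the defaults reproduce
the expected sign structure: more reference length (less pre-tension) ⇒
more joint motion; more stiffness ⇒ less motion; more load ⇒ more of
everything. `perturbation_study()` covers the discrete checks (gluteal
attachment shifts of 10 mm medial / 20 mm lateral, linear vs exponential
contact, friction 0.2–0.6, overclosure scaling), and `convergence_study()`
re-solves one scenario across the coarse/medium/fine grids (element count
roughly doubling and quadrupling) and reports relative differences against
the finest level, using the symmetric xyz scenario — the one with the
largest average stresses and joint movements — by default.

## Problem sizes and runtimes

The desk-scale coarse grid is ≈ 3,400 elements (≈ 1,100 nodes); medium and
fine refine by ×1.3 and ×1.7 per axis with all patch windows preserved
exactly (grid lines are pinned at patch boundaries). A full coarse solve
(pre-tension ramp plus five load increments) takes a few seconds. The test
suite exercises the solver-heavy paths at reduced resolution multipliers
(0.45–0.6 of coarse) to keep the default run short; `run_study()` defaults
to the full coarse grid and reproduces the complete study design
(2 morphology variants × 8 generic scenarios × 5 gait phases, plus the
three-input sensitivity table) deterministically under a fixed seed.

## Known limitations

* Geometry is a parametric surrogate; no anatomical surface detail, no
  statistical shape variation.
* Bone is isotropic linear-elastic; no cortical/trabecular constitutive
  split beyond the density contrast, no viscoelasticity.
* Ligaments are linear tension-only springs (no toe region); muscles are
  passive.
* Contact ignores meshed cartilage volumes, wear and lubrication; the
  small-sliding pairing assumes joint motions small against the facet size.
* The synthetic gait curve matches only the printed per-component force
  peaks; it is not a measured trial, and the contralateral side is unloaded
  during gait phases by default.
* Element formulation is the linear tetrahedron, which is stiff in bending;
  the mesh-convergence study is the instrument for judging discretization
  error.
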
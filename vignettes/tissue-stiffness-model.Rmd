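---
title: "A membrane finite-element model of extensometer experiments on epidermal tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A membrane finite-element model of extensometer experiments on epidermal tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellstretch)
```

## The scientific question

When a strip of plant epidermis is clamped in a microextensometer and
stretched, the recorded force–displacement curve reflects three things at
once: the stiffness of the cell-wall material, the turgor pressure inside
the cells, and the geometry and arrangement of the cells themselves.
Epidermal peels of onion are the classic system: a single layer of long,
thin, staggered cells. Tensile tests consistently find the tissue stiffer
along the cell axis than across it — yet elongated cells are usually
thought to grow along their *softer* wall direction. `cellstretch`
implements a cell-resolved mechanical model of the stretching experiment
so that the contribution of geometry can be separated from the material:
it builds idealized 3D templates of a cellular monolayer, pressurizes the
cells, simulates clamped stretching, and converts the reaction forces into
the same stress–strain quantities an experimentalist would report.

## The mechanical model

Cell walls are thin relative to cell size, so each wall is a hyperelastic
**membrane**: flat 3-node triangles with an in-plane deformation gradient
$F \in \mathbb{R}^{3\times2}$ (the tangent map from the reference plane of
the element to its deformed position), no bending stiffness, and a
per-element thickness $t$. The equilibrium configuration minimizes the
total potential

$$\Pi(u) \;=\; W_E(u)\;-\;\sum_{c}\,P\,\bigl(V_c(u)-V_c^0\bigr),$$

where $u = x - x_0$ is the nodal displacement field, $W_E$ the elastic
energy of all wall elements, $P$ the turgor pressure and $V_c(u)$ the
volume enclosed by cell $c$'s closed, outward-oriented triangulated
surface, evaluated by the divergence theorem
($V = \tfrac16\sum_f x_1\cdot(x_2\times x_3)$). Writing the pressure as
$-P\,V(u)$ makes it a *follower* load — always normal to the deformed
faces — without any surface-traction bookkeeping.

### Constitutive laws

The wall material is Saint Venant–Kirchhoff (SVK): quadratic in a chosen
strain measure $E$,

$$W \;=\; \tfrac{\lambda}{2}\,\mathrm{Tr}(E)^2 + \mu\,\mathrm{Tr}(E^2),
\qquad
E = \mu_E\frac{3\lambda+2\mu}{\lambda+\mu},\quad
\nu = \frac{\lambda}{2(\lambda+\mu)} .$$

Two strain measures are implemented:

* **Biot (engineering) strain**, $E_{\mathrm{Biot}} = U - I$ with $U$ the
  right stretch tensor from the polar decomposition $F = RU$ (computed by
  SVD, which stays well-behaved for nearly degenerate elements). With
  $\nu = 0$ an isotropic Biot-SVK sheet under uniaxial stretch has an
  *exactly linear* nominal-stress/strain response of slope $E$ — the
  package's flat-sheet patch test checks this to machine precision. This
  is the default for isotropic walls, as it avoids the spurious
  large-strain stiffening of the Green measure.
* **Green–Lagrange strain**, $E_G = (F^\top F - I)/2$, the conventional
  SVK choice, used by the transversely isotropic wall model.

The transversely isotropic law is an orthotropic quadratic energy in
$E_G$ expressed in a per-element material frame whose first axis is the
projection of the global longitudinal direction onto the element plane:

$$W = \tfrac{E_\ell}{2}E_{11}^2 + \tfrac{E_t}{2}E_{22}^2 + 2G\,E_{12}^2,
\qquad G = \tfrac{\sqrt{E_\ell E_t}}{2}.$$

With $\nu = 0$ (the default throughout) there are no coupling terms, and
the shear choice makes the law reduce *exactly* to the isotropic SVK when
$E_\ell = E_t$ and treat the two axes symmetrically. Elements whose plane
is nearly perpendicular to the longitudinal axis (transverse end walls)
contain no longitudinal direction; they carry $E_t$ isotropically. A
membrane cannot strain normally to its plane, so the normal-direction
modulus is inert metadata. Per-element Cauchy stress is recovered as
$\sigma = J^{-1} P_K F^\top$ (with $P_K$ the first Piola–Kirchhoff
stress and $J = \det U$) and its trace is the heatmap quantity written to
VTK output.

Default material parameters: isotropic $E = 100$ MPa, $\nu = 0$,
$P = 0.5$ MPa for turgid and $0.01$ MPa for plasmolyzed tissue; the
anisotropic runs use $E_\ell = 30$, $E_t = 100$ MPa.

### Solver

Equilibria are found by pseudo-transient continuation (an implicit
backward Euler step on the gradient flow): each accepted update is

$$u \leftarrow u - \Delta t\,\bigl(I + \Delta t\,\mathbb{H}\bigr)^{-1}
\nabla\Pi(u)$$

on the free degrees of freedom, where $\mathbb{H}$ is the Hessian of
$\Pi$. Gradients are assembled analytically per element (for the Biot
measure via $\partial W/\partial F = R\,T$, exploiting that the
conjugate stress $T$ commutes with $U$ for an isotropic law); the Hessian
is obtained by forward finite differences of the analytic *element*
gradients (step $10^{-6}$ µm, locally symmetrized), which preserves the
element-locality sparsity pattern at a cost of ten gradient evaluations
per element. $\Delta t$ starts at 0.1, doubles after every
full energy-decreasing update and halves when a trial fails; at the
$\Delta t$ cap ($10^6$) an update is numerically a full Newton step,
giving quadratic tail convergence. Before a failed trial triggers a
refactorization at smaller $\Delta t$, the computed direction is first
backtracked (step fractions 1, 1/2, 1/4, 1/8) — damping a step costs one
energy evaluation instead of a new factorization and preserves the
energy-decrease guarantee. Convergence is declared when the free-DOF
residual reaches $10^{-4}$ µN in the infinity norm — roughly $10^{-6}$
of the reaction forces in a stretching run. Linear systems use a cached
supernodal Cholesky factorization (CHOLMOD via `Matrix`), with the
symbolic analysis and all sparse-pattern bookkeeping precomputed once per
mesh. Indefinite shifted matrices (common while nearly unpressurized
flat walls buckle into shape) are handled by step rejection and damping,
never by modifying the Hessian; after the first supernodal failure an
equilibration switches to a simplicial LDL' factorization, which factors
indefinite matrices without erroring, and periodically probes the faster
supernodal path again.

Rigid-body modes: a pressurized free template is fixtured with a
statically determinate 3-2-1 pin set (pressure loads are globally
self-equilibrated, so the pins carry no force and do not distort the
deformation). During stretching only the stretch-axis coordinate of the
end nodes is prescribed, plus one interior node pinned in the two
orthogonal axes; the remaining axial-rotation mode is energetically
neutral and harmless to the damped update.

## The synthetic tissue generator

Templates emulate an onion epidermal peel as a monolayer of rounded
cuboid cells:

1. **2D tiling** — rectangles of `cell_width` (20 µm) by
   `cell_width * aspect_ratio` on a lattice of `vertex_spacing` (2 µm),
   optionally staggered by half a cell length (snapped to the lattice);
   border-straddling cells are truncated and closed flat, and truncated
   slivers narrower than two lattice units are merged into neighbors.
2. **Extrusion** — five 4 µm segments through the 20 µm depth. Adjacent
   cells share a single welded wall only within a central band of 1/3 of
   the depth (band edges get exact extra ring lines); outside the band
   facing walls are coincident but topologically separate, so every cell
   surface is closed and cells can detach except at the band.
3. **Rounding** — `smooth_template()` first applies a deterministic
   elliptic profile rounding (corner radius 5 µm, capped per cell at
   0.15 of the smaller cell dimension, i.e. 3 µm for the standard
   20 µm-wide cells) that curves the anticlinal walls inward outside the
   band, so cells become rounded cuboids touching only at the connection
   band; then Taubin-style shrink-compensated Laplacian sweeps
   ($\lambda = 0.5$, $\mu = -0.53$, 10 iterations by default) relax the
   remaining corners. Central-segment vertices and template borders stay
   fixed; the radius cap keeps every cell's volume change below 20%
   (at most 17% across the packaged template family). A plain shrinking
   Laplacian is available (`mu = 0`) but at useful strengths it violates
   that volume bound on truncated cells.

The only free mechanical scale is the uniform wall thickness: membrane
stiffness is linear in it. It is fixed — once — by
`calibrate_wall_thickness()`: the staggered 5:1 template pressurized to
0.5 MPa must gain approximately 15% in cell volume. At the desk-scale
resolution used throughout the tests this gives **1.71 µm**.

The generator also produces synthetic raw extensometer traces (toe
region, linear elastic rise, Gaussian force noise, seeded RNG) so the
curve-analysis functions can be exercised against known ground truth.

What the generator does *not* emulate: real onion cell-shape variability
(a segmented template can be imported via `read_vtk_template()` instead),
non-uniform wall thickness, the thick outer periclinal wall, plasticity
and rupture, and any contact mechanics — coincident walls of neighboring
cells may interpenetrate under pressure, as in the modeling tradition
this follows. Passing tests therefore demonstrate correctness of the
mechanics and the analysis pipeline on idealized geometry, not fidelity
to any particular onion.

## The virtual extensometer and curve analysis

`pressurize()` equilibrates the free template under turgor and reports
the relative enclosed-volume gain. `stretch()` then holds one end's
stretch-axis coordinates at their pressurized positions and displaces the
other end in equal increments (default protocols: 50% total strain for
curve panels, 20% with 10 steps for the quantitative reference point),
re-equilibrating after each increment and summing the reaction force —
the energy gradient at the constrained DOFs — over the displaced nodes.
Displacement and force are logged relative to the pressurized
equilibrium, whose extent along the stretch axis also serves as the
reference length for strain; lateral edges are free, as in the physical
instrument. Elastic equilibrium is path independent, so the curve is
step-count independent (checked to 2% at 20% strain).

`to_stress_strain()` divides force by the reference cross-section (width
times anticlinal depth) and displacement by the reference length;
`stress_at_strain()` reads the 20%-strain reference stress by linear
interpolation; `stiffness_ratio()` forms the longitudinal/transverse
anisotropy ratio. For experimental-style raw curves, `remove_toe()`
drops the leading near-zero-force region and re-zeros displacement.

`fit_longitudinal_fraction()` estimates how much softer the longitudinal
wall direction must be for the simulated tissue ratio to match a target
(for example, the ratio measured on plasmolyzed tissue): the achieved
ratio is monotone in $E_\ell/E_t$ — verified on the bisection trace — so
a bisection over $(0,1]$ suffices; each candidate runs the full
two-direction pipeline. Because the anisotropic law uses Green strain,
stresses at 20% engineering strain are inflated by the secant factor
$E_G(\varepsilon)/\varepsilon = 1+\varepsilon/2 = 1.1$; the fit divides
both directions by this factor (recorded as `linearized` in the result)
so values are comparable with Biot-measure runs. The correction cancels
in the ratio itself; it matters when individual stresses are compared
across strain measures.

## Numerical and design choices

* Units: lengths µm, moduli and pressures MPa, forces µN
  (MPa·µm² = µN) — no unit conversions anywhere.
* Degenerate elements (area Jacobian below $10^{-10}$) abort assembly
  with the element id; mesh generation rejects non-manifold wall
  pairings and non-positive cell volumes outright.
* Triangulation diagonals alternate by lattice parity, chosen
  canonically per wall quad so both adjacent cells generate identical
  band triangles (deduplicated into single welded elements).
* The Hessian pattern, its CSC slot maps and the symbolic factorization
  are cached per mesh; within a stretch the pseudo-time step is warm
  started from the previous increment and the initial guess is an affine
  extrapolation of the increment, which keeps re-equilibration to a few
  Newton-like iterations.
* Interrupting CHOLMOD mid-factorization (e.g. by an R warning handler)
  corrupts its workspace; the solver therefore muffles warnings and
  reacts only to the final error when a trial factorization fails.

## Problem sizes and what the packaged runs use

The quantitative runs in the tests and the acceptance script use the
desk-scale resolution: vertex spacing 4 µm and halved template extents
(via `coarsen_spec()`), i.e. meshes of roughly 7–25 thousand nodes, with
10 displacement increments to 20% strain. Unit and property tests use
one- and two-cell templates (a few hundred nodes). Full-resolution
templates (2 µm spacing, 300 µm or 600 µm extents) are supported and
produce the same qualitative behavior at several-fold cost.

## Known limitations

* **Absolute stress levels versus the volume calibration.** With the
  thickness fixed by the 15% pressurization-volume condition, the
  simulated 20%-strain stresses on these templates sit well above the
  published reference values (longitudinal roughly 5 MPa versus 2.44).
  The two conditions pull against each other for any uniform-thickness
  membrane template of this family: the wall content needed to reproduce
  the longitudinal stress (about 0.12 of the cross-section, i.e.
  $t\approx0.6$–0.7 µm) admits a pressurization volume gain well above
  15% (the pure hoop-stretch contribution alone is
  $\sim 2PR/(Et)\approx16$%, before any unfolding of flat wall regions).
  The original templates were produced by an external tool whose exact
  rounding and wall-sharing conventions are not documented; their
  geometry evidently distributes wall material differently. We follow
  the volume-calibration prescription, so the thickness-insensitive
  quantities — the 5:1 anisotropy ratios and the pressurization volume
  gain — are what this package reproduces most closely, while absolute
  stress levels carry the calibration tension and are reported as-is.
* **Staggering statistics.** In this template family, staggering changes
  the stiffness ratio at 2:1 by about 11% and reduces transverse stress
  by about 5% on average across aspect ratios — qualitatively the right
  direction and ordering (largest effect for short cells), but several
  times weaker than in the reference geometry. The effect evidently
  depends on fine features of the cell shapes near the junctions that
  the idealized rounded cuboids do not capture.
* The transverse response of coarse meshes is slightly stiff (wall
  unfolding is under-resolved at 4 µm spacing); refining to 2 µm moves
  transverse stresses by only a few percent in our checks.
* Purely elastic: no plasticity, rupture, viscoelasticity; no contact
  between interpenetrating walls; no bending energy.

## Reproducing the packaged numbers

`run_paper_suite()` executes the staggering comparison, the plasmolyzed
runs and the aspect-ratio sweep and writes curves, a summary table and
staggering statistics. `scripts/acceptance.R` (repository root) recomputes
the headline quantities from scratch against the installed package and
writes them to JSON; see the README for how to run it.
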
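---
title: "Methods: gradient-FSS chamber flow, cell-scale Stokes solves, and RAV polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-FSS chamber flow, cell-scale Stokes solves, and RAV polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gradfss` simulates the fluid shear stress (FSS) experienced by adherent
cells in a wedge-shaped parallel-plate flow chamber and quantifies how the
transverse FSS gradient polarizes the stress distribution over each cell's
dorsal surface.  This vignette is the package's own account of the models,
the numerical choices behind them, and what the tests do and do not
establish.

## The chamber and its background flow

The chamber is a rectangular channel, width $w$ = 12 mm, length $l$ = 50 mm,
whose cover leans across the width: the gap height grows linearly from
$h_1$ = 0.2 mm to $h_2$ = 0.8 mm.  The coordinate convention, fixed
repo-wide, is $x$ the width/gradient axis (0 at the shallow side), $y$ the
flow axis (0 at the inlet), $z$ the height (0 at the floor).  A pressure
difference $\Delta p$ along $y$ drives laminar flow of a Newtonian medium
($\rho$ = 1000 kg/m$^3$, $\mu$ = $10^{-3}$ Pa s).

Because the cover slope $dh/dx = 0.05$ is small, each width station behaves
as a plane Poiseuille flow of local height $h(x)$, giving the lubrication
closed form for the floor wall shear stress,

$$\tau_w(x) = \frac{h(x)\,\Delta p}{2 l},$$

which is linear in $x$ because $h$ is.  With inlet 300 Pa and outlets
{200, 100, 0} Pa this yields transverse gradients of 0.05, 0.10 and 0.15
Pa/mm by the closed form.  (For the largest pressure drop the device is
often described by a nominal 0.2 Pa/mm; the closed form gives 0.15 Pa/mm
and the package reports conditions by their computed gradient.  The RAV
grids therefore take the gradient, not the pressure drop, as the condition
label, and run {0.05, 0.1, 0.2} Pa/mm in *imposed* mode, where the local
background is prescribed directly.)

The lubrication formula is validated by a fully developed cross-section
solve: $\mu \nabla^2 u_y = -\Delta p / l$ on the trapezoid
$0 \le z \le h(x)$ with no-slip walls, discretized with second-order
central differences in the height-mapped coordinate $\eta = z/h(x)$
(including the metric cross terms) and solved directly with a sparse LU.
On a 256 x 64 grid the interior floor shear agrees with lubrication to
0.02% and its least-squares slope over $x \in [2, 10]$ mm — the window
that excludes the side-wall boundary layers — is 0.05 Pa/mm for
$\Delta p$ = 100 Pa with $R^2 > 0.999$.  Entrance effects are outside the
model: the flow is fully developed by construction, which matches the
y-invariant velocity the device is designed for.

## Local flow around the cells

Cells are spherical caps of radius $a$ = 10 µm (hemispheres by default; the
contact angle is configurable because the true adherent geometry is not
known) sitting on the floor, either isolated or in a hexagonal packing —
one central cell with six neighbours at centre distance $d = 2a\sin\theta_c
+ s$ for surface gap $s$.

A cell is three orders of magnitude smaller than the chamber, so the
package uses a submodel: steady incompressible Stokes flow in a box around
the arrangement, with the background shear imposed on the box faces,

$$v_y(x, z) = \frac{\tau_0 + g\,(x - x_c)}{\mu}\, z,$$

carrying both the local magnitude $\tau_0$ and the transverse gradient
$g$.  The box extends 5 cell radii beyond the outermost cell laterally and
5 radii vertically; the channel's quadratic velocity correction is dropped
(the box top sits at $\le$ 25% of the local channel height, and the
correction affects both gradient-facing sectors symmetrically).  Cell
Reynolds numbers are ~$10^{-3}$, so the creeping-flow approximation and
the one-way coupling back to the channel are both safe.

Discretization: a staggered (MAC) finite-difference grid, default spacing
2.5 µm (8 cells per cell radius).  The cell bodies enter through smoothed
volume penalization — a Brinkman drag $\eta \chi u$ with $\chi$ the solid
fraction ramping linearly across one grid cell at the surface and $\eta =
10^4 \mu/\Delta^2$, giving a residual interior slip ~$10^{-4}$ of the flow
scale and smooth behaviour under refinement.  Incompressibility is
enforced by an augmented-Lagrangian outer loop ($p \leftarrow p - \lambda
\nabla\!\cdot u$, $\lambda = 20\mu$, four iterations) around a matrix-free
Jacobi-preconditioned conjugate-gradient solve of the penalized momentum
operator (relative tolerance $10^{-8}$; the stencil is compiled code).
The empty-domain solve reproduces an imposed linear shear to machine-level
accuracy, which anchors the floor-FSS oracle checks.

Surface traction is evaluated from the full stress tensor $\sigma = \mu
(\nabla u + \nabla u^T) - p I$ at probe points offset $1.5\Delta$ along
the outward normal (outside the penalization smoothing layer); the scalar
wall FSS is the magnitude of the tangential component.  The FSS so defined
is a near-surface sample rather than the singular boundary limit; it is
used consistently everywhere, and the RAV statistic — a ratio of sector
means — is insensitive to the common scale.  Stress is singular at the
contact line, so nodes below 2° elevation are excluded from all
statistics (configurable).  Total drag is measured as the Brinkman force
integral $\sum \eta \chi u\, \Delta V$, the discrete momentum balance,
which converges under refinement (1.55 nN at the default grid vs 1.51 nN
at 1.5 µm for $\tau_0$ = 1 Pa on a hemisphere).

Stokes flow is linear in its boundary data, and the solver preserves that
linearity exactly (conjugate gradients from a zero start is homogeneous of
degree one).  The pipeline exploits it: per arrangement geometry only two
unit solves are run (unit $\tau_0$, unit $g$), and every condition is a
superposition of the two nodal traction fields.  One consequence of the
fully developed background is that replicates along the flow axis are
physically identical, so replicate tables carry zero SD by construction —
the replicate axis documents the study design rather than adding
information.

## The hyperelastic cell

The cell is a compressible isotropic neo-Hookean (Hookean hyperelastic)
solid with energy density

$$W_s = \tfrac{G}{2}(I_1 - 3) + \tfrac{\Lambda}{2}(\ln J)^2 - G \ln J,
\qquad G = \frac{E}{2(1+\mu_p)},\quad
\Lambda = \frac{E \mu_p}{(1+\mu_p)(1-2\mu_p)},$$

with $E$ = 5000 N/m², Poisson ratio $\mu_p$ = 0.3 (so $G$ = 1923, $\Lambda$
= 2885 N/m²) and density 1100 kg/m³.  $W_s$ vanishes exactly on rigid
motions and is non-negative for admissible deformations ($-1 < \mu_p <
0.5$).  The volume is meshed by radially scaled copies of the surface mesh
(prisms split into tetrahedra by the minimum-vertex rule, a star layer to
the centre), so fluid tractions map one-to-one onto the outer layer.  The
base ($z = 0$) is fully fixed — the adhesion constraint is not otherwise
specified, and a fully clamped base is the stiffest (most conservative)
choice.  Equilibrium minimizes strain energy minus external work with
L-BFGS on a nondimensionalized problem (lengths by $a$, energy by
$E a^3 s^2$ with $s$ the load scale), with analytic first
Piola–Kirchhoff gradients.  At chamber loads the response is linear and
the peak displacement is ~$\tau/E \sim 10^{-4}$ of the radius, which is
the quantitative basis for one-way coupling; no deformation results are
available to compare against, so the solid solve is validated by its
invariants (frame indifference, energy non-negativity, the small-strain
limit against Hooke's law, load linearity).

## Sectors, bands, RAV

The dorsal surface is quartered by azimuth about the gradient direction:
SHFSS is the 90° sector facing the higher-FSS side, SLFSS the opposite
one, with two lateral quarters between (boundary azimuths go to the
counter-clockwise sector).  Bands are rings of elevation 30°/45°/60° from
the floor plane through the sphere centre, half-width 7.5° (no value is
prescribed for the half-width; 7.5° keeps the three bands disjoint with
comfortable node counts).  30° lies near the adhesion region, 60° near the
apex.

RAV is the ratio of the area-weighted mean FSS in SHFSS to that in SLFSS.
Because an unpolarized cell should score zero, the package reports
`rav = ratio - 1` as the headline statistic and exposes the raw ratio
alongside.  Sector and band means are genuine surface integrals: each
triangle is subdivided 16-fold per edge, the piecewise-linear field is
evaluated at sub-centroids, and sector/band membership is decided per
quadrature point.  (Assigning whole nodes to sectors biases the means near
the apex, where azimuth is ill-defined but area density maximal; the
quadrature form recovers prescribed polarizations within 1% of the
independent closed-form integral at the default mesh.)  Area weighting —
rather than node averaging — makes the means independent of mesh density.

## The synthetic generator

`synth_surface_field()` produces closed-form fields
$\tau_0 \sin(\theta_e)^k (1 + \varepsilon \cos\phi)$ plus optional
seeded Gaussian node noise, and `synth_background_profile()` linear
profiles $\tau_0 + g x$.  These emulate the *statistical structure* of
solved fields — the apex-high elevation shape and an azimuthal
polarization of known amplitude — so the entire analytics chain can be
tested against direct quadrature without a PDE solve.  They deliberately
do not emulate the near-contact-line stress behaviour, neighbour
shielding, or the coupling between elevation and azimuth that real
solved fields show; passing the synthetic recovery tests therefore
validates the analytics, not the solver, which has its own oracle chain
(empty-domain exactness, linearity, symmetry, drag and mesh-refinement
convergence).

## Problem sizes and reproducibility

Default sizes keep a full study desk-sized: 256 x 64 for the cross-section
solve, 2.5 µm grids (48³-scale boxes) for local solves, surface meshes of
545 nodes (subdivision level 4), two unit solves per geometry.  The
qualitative RAV findings — positive under every nonzero gradient, growing
with the gradient at fixed 0.1 Pa, falling with magnitude under steeper
gradients, and largest in the 30° band — are reproduced at these
resolutions with comfortable margins.  Everything is deterministic: the
solvers have no random state, synthetic noise requires an explicit seed,
and re-running a configuration reproduces its tables bit-identically.

Known limitations: one-way coupling only (no geometry feedback into the
flow); stair-free but first-order-smooth penalized boundaries rather than
body-fitted meshes; the 2 µm hexagonal gap is below the default grid
spacing, so near-contact lubrication in that gap is under-resolved (the
shielding it produces is captured, its fine structure is not); no
entrance-region or transient effects; and no statistical significance
machinery — replicates are identical by design, so the package reports
means and (zero) SDs, not tests.
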
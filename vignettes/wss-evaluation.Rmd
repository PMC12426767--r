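---
title: "Evaluating wall shear stress with mixed finite elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating wall shear stress with mixed finite elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wssbench)
```

Wall shear stress (WSS) — the tangential component of the traction a flowing
fluid exerts on a vessel wall — is one of the most used quantities in
computational hemodynamics, yet its numerical value depends strongly on *how*
it is extracted from a finite-element flow solution.  `wssbench` implements
the two standard extraction families side by side and provides the analytic
benchmarks to compare them: an $L^2$ projection of the tangential traction
onto a boundary space (continuous P1 or discontinuous DG-1/DG-0), and a
variationally consistent *boundary-flux* evaluation that recovers the wall
traction from the discrete momentum residual.  This vignette describes the
models, the discretizations, the numerical choices, and what the packaged
benchmarks do and do not demonstrate.

## Flow models and discretization

The package solves stationary Stokes flow
$$-\operatorname{div} T(v, p) = f, \qquad \operatorname{div} v = 0,$$
with either the full-gradient stress $T = -pI + \nu \nabla v$ or the
symmetric form $T = -pI + 2\nu D(v)$, $D(v) = \tfrac12(\nabla v + \nabla
v^\top)$, and steady Navier–Stokes flow obtained by pseudo-time marching (see
below).  All benchmark runs divide the momentum equation by density, so
reported pressures and stresses are density-scaled; `fluid_properties()`
records this convention explicitly.

Two mixed elements are supported on simplicial meshes:

* **Taylor–Hood P2/P1** — inf-sup stable, quadratic velocity and linear
  pressure, Dirichlet data normally imposed strongly;
* **stabilized equal-order P1/P1** — linear velocity and pressure made stable
  by penalizing inter-element jumps.  For Stokes runs this is the continuous
  interior-penalty (CIP) form
  $$S = \sum_K \tfrac12 \int_{\partial K} \gamma_p h_K^{s+1}
  [\![ n\cdot\nabla p]\!] [\![ n\cdot\nabla q]\!]
  + \tfrac12 \int_{\partial K} \gamma_v h_K^{s+1}
  [\![ \operatorname{div} v]\!] [\![ \operatorname{div} w]\!],$$
  with the exponent rule $s = 2$ where $\nu \ge h_K$ and $s = 1$ otherwise,
  evaluated cell by cell ($h_K$ is the circumdiameter, the diameter of the
  cell's circumscribed circle or sphere).  The defaults follow the benchmark
  protocol: $\gamma_p = \gamma_v = 10^{-2}$ on the unit square,
  $\gamma_p = 1$, $\gamma_v = 10^{-3}$ on the cylinder.  For Navier–Stokes
  runs an $h^2$-scaled interior-penalty variant with full gradient jumps and
  a convective $(v\cdot n)^2$ weight is used instead, with weights
  $\alpha_v = 10^{-3}$, $\alpha_p = 1$, $\alpha_i = 10^{-3}$.

Dirichlet conditions can be enforced strongly or weakly by the
**non-symmetric Nitsche method** with penalty $\beta\nu/h$:
$$N(v_{bc}; v,p,w,q) = -\int_{\Gamma_D} T(v,p)n\cdot w
 + \int_{\Gamma_D} T(w,q)n\cdot(v - v_{bc})
 + \frac{\beta\nu}{h}\int_{\Gamma_D} (v - v_{bc})\cdot w.$$
The method is well posed even for $\beta = 0$; the package default is
$\beta = 10$, a conventional penalty scale that we use unchanged in every
study.  Weak enforcement is essential for the stabilized P1/P1 pair, whose
optimal convergence is otherwise lost; Taylor–Hood runs use strong
enforcement.

The equal-order pair requires nonzero pressure stabilization; this is
enforced at configuration time.  Dirichlet-only problems fix the pressure
gauge by a scalar Lagrange multiplier enforcing $\int_\Omega p = 0$ exactly.

## WSS extraction

With outward unit normal $n$, the wall traction is $t = T(v,p)n$ and the WSS
is its tangential part $\tau = t - (t\cdot n)n$.  Two recovery routes:

**Projection.**  Solve
$\int_{\Gamma_w} \tau\cdot\phi = \int_{\Gamma_w} (Tn - (Tn\cdot n)n)\cdot\phi$
for $\tau$ in P1 (continuous), DG-1 or DG-0 on the wall facets.  The pressure
part of $Tn$ is purely normal and drops out, so only the viscous stress is
evaluated.  DG spaces invert facet-local mass matrices; the continuous system
is assembled over the whole scalar space with non-wall rows replaced by the
identity (interior values exactly zero, mirroring a whole-domain boundary
field with zeroed interior degrees of freedom; a trace-space assembly gives
identical wall values on affine facets).

**Boundary-flux evaluation.**  Test the discrete momentum residual with
boundary-supported functions:
$$\int_{\Gamma_w} \tau_b\cdot\phi =
 \rho\int_\Omega (\partial_t v + (\nabla v)v)\cdot\phi
 + \int_\Omega T : \nabla\phi - \int_\Omega f\cdot\phi + S(v,p;(\phi,0))
 - \int_{\Gamma_w} (Tn\cdot n)(n\cdot\phi)
 - \int_{\Gamma_{in}} Tn\cdot\phi - \int_{\Gamma_{out}} Tn\cdot\phi,$$
with the convection/time terms present for Navier–Stokes solutions (at the
converged steady state the BDF2 time-derivative term is negligible by the
steady tolerance, but it is assembled from the final stencil for
completeness).  When the solution was obtained with Nitsche enforcement, the
transpose-consistency and penalty terms remain on the right-hand side.  We
retain them on *every* Nitsche-enforced Dirichlet segment, not only the wall:
with this choice the boundary-flux recovery in P1 is *algebraically
identical* to the P1 projection for stabilized P1/P1 solutions whenever all
boundary segments are Dirichlet — the property the test suite checks to
$10^{-6}$ relative — because the tested residual telescopes to the facet
quadrature of the discrete traction.

Boundary fluxes are known to lose accuracy at corners where boundary
segments with different tangent planes meet.  On the unit square every
recovery in a *continuous* space is therefore computed segment by segment
(the other segments entering as subtracted Neumann data) and the per-segment
fields are combined facet-wise, each corner keeping its one-sided values.
This restores the interior convergence rate; without it the corner
singularity of the exact WSS (which jumps at the upper-right corner of the
benchmark square) contaminates the whole-boundary projection at rate
$\mathcal{O}(h^{1/2})$.  Facet-local DG spaces need no segmentation.

Normals are facet-wise outward normals used inside all integrals; no nodal
normal averaging is performed, since a vertex normal is not well defined on
a faceted surface.  Quadrature on boundary facets uses degree $2k+1$ rules
for velocity degree $k$ — shared between the solver's Nitsche terms and both
WSS evaluators, which is what makes the projection/boundary-flux identity
exact at the discrete level.  Volume terms use the solver's residual degree.

## Analytic benchmarks

**Unit square (2D Stokes).**  The manufactured solution
$v = (20xy^3,\; 5x^4 - 5y^4)$, $p = 60x^2y - 20y^3 - 5$ satisfies the Stokes
system exactly with $\nu = 1$, $f = 0$ and full-gradient stress; the pressure
has zero mean.  Both facts are verified at construction time by evaluating
the polynomial divergence and momentum residuals on a grid with more points
per direction than the polynomial degree (a polynomial-identity test;
Richardson-extrapolated differences make the derivative checks exact to
roundoff).  The exact WSS vanishes on the left and bottom sides, is $(0,20)$
on the right and $(60x, 0)$ on the top.  Meshes are crossed-diagonal
("union-jack") triangulations, symmetric about both axes, with $N$
subdivisions per side.

**Cylinder (3D Poiseuille).**  Radius $R = 1$ mm, length $L = 2$ mm, axis
along $z$; parabolic inflow with centreline velocity $u_m = 1$ m/s (mean
$\bar v = 0.5$ m/s), no-slip wall, and an outlet with zero in-plane velocity
components and natural normal stress.  With dynamic viscosity
$\mu = 4\,\mathrm{mPa\,s}$ the exact wall WSS magnitude is
$2\mu u_m/R = 8$ Pa (density-scaled), directed against the flow.  The
symmetric stress form is used, matching the do-nothing outlet that the exact
solution satisfies.  Cylinder meshes are generated by the package's own
structured mesher: a hexagonal-ring disk triangulation (ring $j$ carries
$6j$ points) extruded along $z$, each prism split into three tetrahedra with
diagonals chosen from the smaller global bottom index so neighbouring prisms
conform.  The boundary-layer family replaces the outermost rings by four
graded layers of heights $0.1e\cdot 1.1^k$ (wall-finest), $e$ the surface
edge length, transitioning into the uniform core — a total stack thickness
of $0.4641\,e$.  Because the mesher differs from the commercial generator
used in the original experiments, absolute errors and element counts differ;
fitted convergence rates are the comparison surface.  One visible
consequence: on these structured meshes the P1/P1 pressure error on the
cylinder decays at a rate close to 2, noticeably better than the published
1.61 obtained on unstructured meshes — a mesh-family superconvergence effect,
not a discrepancy in the discretization.

The study resolutions are fixed in `benchmark_suite_levels()`:
$N = 8 \dots 128$ (P1/P1) and $8 \dots 128$ (P2/P1) on the square, and
target edge lengths $R/3 \dots R/8$ on the cylinder, with three levels for
the heavier Taylor–Hood and boundary-layer runs.  These sizes keep each
study within a few minutes on a single CPU while remaining in the asymptotic
regime of the fitted rates; the fits use all levels, and a drop-the-coarsest
stability check in the test suite guards against preasymptotic
contamination.

## Steady Navier–Stokes by pseudo-time marching

Image-based runs solve the incompressible Navier–Stokes equations to steady
state: start from rest, ramp the inflow linearly over 0.5 s, march with
variable-step BDF2 and Newton's method, and stop when the $L^2$ norm of the
discrete time derivative falls below $10^{-5}$ (or $t \ge 10^6$ s).  The
paper-level protocol leaves the step controller unspecified; ours multiplies
$\Delta t$ by 1.5 after a Newton solve that converges in at most four
iterations, halves it on divergence, and clips to $[10^{-2}, 10^5]$ s.
Newton stops at an absolute residual of $10^{-10}$ or a relative reduction
of $10^{-8}$.  The convective weight of the interior-penalty stabilization
is evaluated at the previous time level (it enters as a lagged coefficient,
keeping the Jacobian exact for the remaining terms).  The full `dt` history
is kept in the returned solution for transparency.

## Hemodynamic indicators

`hemodynamic_summary()` reports the max/min/avg WSS magnitude over a tagged
dome region and the low shear area (LSA): the percentage of dome area where
$|\tau|$ falls below 10% of the parent-artery mean WSS, the parent mean
being computed from the *same* WSS field (hence the same recovery method).
Extrema are taken over the method's native evaluation set — facet nodes for
P1/DG-1, facet values for DG-0 — and the LSA thresholds $|\tau|$ at facet
quadrature points, a choice we document because vertex-wise thresholding
would give slightly different areas for fields that straddle the threshold
inside a facet.  The aneurysm geometries themselves are external data; the
package reads tagged MSH 4.1/XDMF meshes with a YAML region map and supports
such runs end to end (`run_experiment()` with `experiment: external_mesh`),
but the shipped benchmarks are the analytic ones.  Fluid properties for
external runs must be supplied by the user; the benchmark values are not
meaningful defaults for a patient-specific artery.

## Numerical choices and degenerate cases

* **Linear solves.**  Saddle-point systems are solved by ILUT-preconditioned
  BiCGSTAB after Ruiz equilibration (three two-norm sweeps), with a
  statically pivoted sparse LU (COLAMD ordering, small diagonal
  perturbation removed again by iterative refinement against the
  unperturbed matrix) as fallback, escalating the pivot threshold only if
  the refined residual exceeds $10^{-10}$.  Partial pivoting on these
  indefinite systems destroys the fill-reducing ordering, which is why the
  statically pivoted route exists.
* **Orientation and tags.**  Cells are reoriented to positive volume at
  construction; every boundary facet carries exactly one region tag, and
  meshes without facet tags are rejected with an "untagged boundary" error.
* **Quadrature.**  Low-order simplex rules are hardcoded; higher degrees use
  the Grundmann–Möller construction (exact by design, possibly with negative
  weights — harmless for the polynomial integrands here; squared norms are
  clamped at zero before the square root).
* **Tangentiality.**  Projection fields are exactly tangential facet-wise
  (DG) or on flat segments (continuous, per-segment); the continuous
  boundary-flux field on a *faceted curved* wall carries a geometric normal
  component of the order of the facet-normal variation, which shrinks under
  refinement — the test suite asserts the hard tolerances on affine
  (flat-segment) configurations and the decay on the cylinder.
* **Ties and degeneracies.**  Boundary-layer stacks thicker than the radius,
  non-positive mesh parameters, empty wall selections, unknown region tags,
  and recovery spaces exceeding the velocity degree are all rejected with
  explicit messages.

## What the benchmarks do and do not show

The analytic benchmarks exercise smooth, laminar, steady flow on simple
geometries with exactly known solutions.  They validate the discretizations,
the recovery operators and their convergence behaviour — including the
counterintuitive result that near-wall boundary-layer refinement *degrades*
Taylor–Hood WSS accuracy on a faceted curved wall (the strongly enforced
no-slip at P2 mid-edge nodes lying inside the true cylinder injects a
geometric error that fine anisotropic cells amplify), and that the
boundary-flux evaluation tested in P1 outperforms its P2 variant there.
They do not emulate pulsatile or transitional flow, moving walls,
image-segmentation noise, or anatomically irregular surfaces; passing them
shows correctness of the numerics, not clinical fidelity of any particular
WSS map.  Single-time-point WSS only is computed; oscillatory indices (OSI,
RRT) and curved (isoparametric) boundary elements are out of scope.
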
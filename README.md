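# wssbench

Finite-element evaluation of wall shear stress (WSS) for incompressible
flow, in R.

Blood-flow-induced WSS — the tangential component of the fluid traction
`T·n` on a vessel wall, in Pa — is a standard hemodynamic indicator, but its
numerical value depends on how it is extracted from a finite-element
solution.  `wssbench` implements, from the mesh up, the two standard
extraction families and the benchmarks to compare them:

* **Flow solvers**: stationary Stokes and steady-state Navier–Stokes
  (BDF2 pseudo-time marching with adaptive steps and Newton iterations),
  discretized with Taylor–Hood **P2/P1** or stabilized equal-order
  **P1/P1** mixed elements on triangles/tetrahedra, with strong or
  non-symmetric **Nitsche** Dirichlet enforcement and continuous
  interior-penalty (CIP) or interior-penalty stabilization.
* **WSS recovery**: L2 projection of the tangential traction
  `τ = Tn − (Tn·n)n` onto P1 / DG-1 / DG-0 boundary spaces, and a
  variationally consistent **boundary-flux** evaluation that recovers the
  wall traction from the discrete momentum residual (testing in P1 or P2),
  including the Nitsche-consistent variant and per-segment corner handling.
* **Benchmarks and indicators**: manufactured 2D Stokes flow on the unit
  square, 3D Poiseuille flow in a cylinder (exact WSS magnitude
  `2 μ u_m / R`), structured mesh generators (crossed unit-square
  triangulations; extruded hexagonal-ring cylinder meshes with optional
  4-layer graded boundary layers), mesh-convergence studies with fitted
  log–log rates, and dome WSS summaries with the low-shear-area (LSA)
  indicator for tagged vascular meshes (MSH 4.1 / XDMF input, YAML region
  maps, VTU/CSV/JSON output).

## A worked example

Solve Poiseuille flow in a 1 mm cylinder with the stabilized P1/P1 element
and recover the WSS by the boundary-flux method:

```r
library(wssbench)

ex    <- poiseuille_exact(R = 1e-3, u_m = 1, mu = 4e-3)   # |tau| = 8 Pa
props <- fluid_properties(kinematic_viscosity = ex$params$nu, density = 1,
                          density_scaled = TRUE)
cfg   <- discretization_config("P1P1_stabilized", "nitsche", beta = 10,
                               stress_form = "symmetric",
                               stabilization = stabilization_weights(
                                 gamma_p = 1, gamma_v = 1e-3))
bcs   <- bc_spec(
  inlet  = list(kind = "dirichlet_nitsche", value = ex$velocity),
  wall   = list(kind = "dirichlet_nitsche",
                value = function(x) matrix(0, nrow(x), 3)),
  outlet = list(kind = "zero_tangential_velocity"))

mesh <- build_cylinder_mesh(1e-3, 2e-3, edge_length = 2.5e-4)
sol  <- solve_stokes(mesh, props, cfg, bcs)
boundary_flux_wss(sol, "wall", "P1")
#> <wss_field> boundary_flux(P1) on 384 facets: |tau| avg 7.412, range [6.954, 7.594]
```

The average magnitude 7.41 Pa sits below the analytic 8 Pa because the
faceted wall underestimates the true cylinder; it converges to 8 under
refinement.  A full convergence study:

```r
s <- run_convergence_study("poiseuille", "P1P1_stabilized",
                           levels = 1e-3 / c(3, 4, 6),
                           wss_methods = c("bflux_p1", "proj_p1"))
round(s$rates, 2)
#>            v            p wss_bflux_p1  wss_proj_p1
#>         2.15         2.00         0.93         0.91
```

`v` and `p` are the fitted L2 convergence rates of velocity and pressure
against the exact fields; the WSS columns are the rates of the recovered
wall shear stress against the exact constant traction.  A command-line
wrapper over the same machinery lives in `inst/cli/wssbench.R`
(`wssbench.R stokes2d|poiseuille|mesh-run --config FILE ...`).

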
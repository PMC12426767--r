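# WSS recovery: tangential projection algebra, facet-local oracles, the
# boundary-flux single-cell oracle, method equivalences and tangentiality.

test_that("tangential_part removes exactly the normal component", {
  expect_equal(tangential_part(c(0, 0, 1), c(0, 0, 1)), c(0, 0, 0))
  expect_equal(tangential_part(c(1, 2, 0), c(0, 0, 1)), c(1, 2, 0))
  expect_equal(tangential_part(c(1, 2, 3), c(0, 0, 1)), c(1, 2, 0))
  # matrix form, arbitrary unit normal: result orthogonal to n
  set.seed(42)
  a <- matrix(rnorm(30), 10)
  n <- matrix(rnorm(30), 10)
  n <- n / sqrt(rowSums(n^2))
  tp <- tangential_part(a, n)
  expect_lt(max(abs(rowSums(tp * n))), 1e-14)
})

test_that("zero velocity yields identically zero WSS for every method", {
  m <- build_unit_square_mesh(4)
  props <- fluid_properties(kinematic_viscosity = 1, density = 1,
                            density_scaled = TRUE)
  cfg <- discretization_config("P1P1_stabilized", "nitsche", beta = 10)
  zero <- function(x) matrix(0, nrow(x), 2)
  sides <- c("left", "right", "bottom", "top")
  bcs <- do.call(bc_spec, stats::setNames(
    lapply(sides, function(s) list(kind = "dirichlet_nitsche", value = zero)),
    sides))
  sol <- solve_stokes(m, props, cfg, bcs)
  for (sp in c("P1", "DG1", "DG0")) {
    wf <- project_wss(sol, sides, sp)
    expect_lt(max(abs(wf$facet_vals)), 1e-11)
  }
  wfs <- wss_per_segment(sol, sides, "boundary_flux", "P1")
  expect_lt(max(abs(wfs$facet_vals)), 1e-10)
})

test_that("DG-0 projection on one facet equals the averaged tangential traction", {
  m <- one_triangle_mesh()
  nu <- 0.5
  vfun <- function(x) cbind(2 * x[, 1] + x[, 2], -x[, 1] + 3 * x[, 2])
  pfun <- function(x) 1 + x[, 1] - 2 * x[, 2]
  sol <- manufactured_solution(m, vfun, pfun, nu)
  wf <- project_wss(sol, "bottom", "DG0")
  # bottom edge: n = (0,-1); grad v constant: rows d/dx, d/dy
  G <- rbind(c(2, -1), c(1, 3))          # [deriv, comp]
  tn <- nu * as.vector(t(G) %*% c(0, -1))
  tt <- tn - sum(tn * c(0, -1)) * c(0, -1)
  expect_equal(as.vector(wf$facet_vals[1, 1, ]), tt, tolerance = 1e-13)
  # constant fields: local mass matrix is the facet length (here 1)
  expect_equal(wssbench:::wss_summary_stats(wf)$area, 1.0, tolerance = 1e-14)
})

test_that("boundary-flux right-hand side matches a dense one-cell quadrature", {
  m <- one_triangle_mesh()
  nu <- 0.8
  vfun <- function(x) cbind(1 + 2 * x[, 1] - x[, 2], 0.5 * x[, 1] + x[, 2])
  pfun <- function(x) 2 - x[, 1] + 3 * x[, 2]
  sol <- manufactured_solution(m, vfun, pfun, nu)
  spw <- sol$space_p
  qrule <- wssbench:::simplex_quadrature(1L, sol$qdeg_facet)
  rhs <- wssbench:::bflux_volume_residual(sol, spw) +
    wssbench:::bflux_boundary_term(sol, spw, which(m$facet_tags == 3L), qrule,
                                   "normal_only") +
    wssbench:::bflux_boundary_term(sol, spw, which(m$facet_tags %in% c(1L, 2L)),
                                   qrule, "full")
  # dense quadrature oracle, assembled term by term with explicit P1 basis
  oracle <- bflux_one_cell_oracle(m, nu)
  expect_equal(as.numeric(rhs), oracle, tolerance = 1e-12)
})

test_that("boundary-flux P1 equals P1 projection for stabilized P1/P1 solutions", {
  fx <- fixture("pois_alldir", function() poiseuille_all_dirichlet_solution())
  wb <- boundary_flux_wss(fx$sol, "wall", "P1")
  wp <- project_wss(fx$sol, "wall", "P1")
  wz <- wp; wz$facet_vals[] <- 0
  rel <- wssbench:::wss_l2_distance(wb, wp) /
    wssbench:::wss_l2_distance(wp, wz)
  expect_lt(rel, 1e-6)
})

test_that("one-segment boundary flux is independent of the segmentation path", {
  fx <- fixture("pois_p1p1", function() poiseuille_p1p1_solution())
  w1 <- boundary_flux_wss(fx$sol, "wall", "P1")
  w2 <- boundary_flux_wss_per_segment(fx$sol, "wall", "P1")
  expect_equal(w1$facet_vals, w2$facet_vals, tolerance = 1e-14)
  d <- wssbench:::wss_l2_distance(w1, w2)
  expect_lt(d, 1e-14)
})

test_that("tags must partition the boundary and spaces must fit the element", {
  fx <- fixture("pois_p1p1", function() poiseuille_p1p1_solution())
  expect_error(boundary_flux_wss(fx$sol, "wall", "P2"),
               "exceeds the velocity degree")
  expect_error(boundary_flux_wss(fx$sol, "wall", "P1",
                                 neumann_tags = "inlet"),
               "partition")
  expect_error(project_wss(fx$sol, character(0)), "unknown|empty")
})

test_that("recovered tractions balance to zero net force on a closed boundary", {
  # All-Dirichlet Stokes with f = 0: summing the boundary-flux right-hand
  # side over the P1 partition of unity gives the net boundary force.  With
  # Nitsche enforcement the retained consistency/penalty terms contribute a
  # residual that vanishes under refinement; the balance must be small
  # relative to the total traction magnitude and improve with resolution.
  net_force <- function(n) {
    fx <- fixture(paste0("p1p1_n", n), function() stokes2d_p1p1_solution(n))
    sol <- fx$sol
    spw <- sol$space_p
    rhs <- wssbench:::bflux_volume_residual(sol, spw) +
      wssbench:::bflux_stabilization(sol, spw) +
      wssbench:::bflux_nitsche_retained(
        sol, spw, wssbench:::simplex_quadrature(1L, sol$qdeg_facet))
    max(abs(colSums(matrix(rhs, ncol = 2, byrow = TRUE))))
  }
  f16 <- net_force(16)
  f32 <- net_force(32)
  # traction scale: int |Tn| over the boundary is O(80)
  expect_lt(f16, 0.01 * 80)
  expect_lt(f32, f16)
  # the volume part alone is in exact equilibrium (partition of unity)
  fx <- fixture("p1p1_n16", function() stokes2d_p1p1_solution(16))
  rhs_vol <- wssbench:::bflux_volume_residual(fx$sol, fx$sol$space_p)
  expect_lt(max(abs(colSums(matrix(rhs_vol, ncol = 2, byrow = TRUE)))), 1e-9)
})

test_that("WSS fields are tangential on flat segments and facet-local spaces", {
  fx1 <- fixture("p1p1_n16", function() stokes2d_p1p1_solution(16))
  sides <- c("left", "right", "bottom", "top")
  expect_lt(wssbench:::wss_tangentiality(
    wss_per_segment(fx1$sol, sides, "projection", "P1")), 1e-8)
  expect_lt(wssbench:::wss_tangentiality(
    wss_per_segment(fx1$sol, sides, "boundary_flux", "P1")), 1e-6)
  expect_lt(wssbench:::wss_tangentiality(
    project_wss(fx1$sol, sides, "DG1")), 1e-8)
  expect_lt(wssbench:::wss_tangentiality(
    project_wss(fx1$sol, sides, "DG0")), 1e-8)
  # facet-local projections are tangential facet-by-facet even on the
  # faceted cylinder; the continuous boundary-flux field carries a
  # geometric normal component that shrinks under refinement
  fx3 <- fixture("pois_p1p1", function() poiseuille_p1p1_solution())
  expect_lt(wssbench:::wss_tangentiality(
    project_wss(fx3$sol, "wall", "DG0")), 1e-8)
  t_coarse <- wssbench:::wss_tangentiality(
    boundary_flux_wss(fx3$sol, "wall", "P1"))
  fx3b <- fixture("pois_p1p1_fine", function() poiseuille_p1p1_solution(1e-3 / 5))
  t_fine <- wssbench:::wss_tangentiality(
    boundary_flux_wss(fx3b$sol, "wall", "P1"))
  expect_lt(t_fine, t_coarse)
  expect_lt(t_fine, 1e-3)
})
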
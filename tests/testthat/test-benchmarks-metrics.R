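# Exact solutions, error norms, rate fitting and hemodynamic indicators.

test_that("the manufactured 2D Stokes solution satisfies its closed forms", {
  ex <- stokes2d_exact()
  expect_equal(ex$pressure(matrix(c(0, 0), 1)), -5)
  # divergence-free: exact gradient trace vanishes on a dense grid
  g <- seq(0, 1, length.out = 9)
  x <- as.matrix(expand.grid(g, g))
  gr <- ex$vel_grad(x)
  expect_lt(max(abs(gr[, 1, 1] + gr[, 2, 2])), 1e-12)
  # mean-zero pressure over the unit square (closed-form integral)
  q <- simplex_quadrature(2, 6)
  m <- build_unit_square_mesh(6)
  geo <- wssbench:::cell_geometry(m)
  xs <- wssbench:::vol_qpoints(m, q)
  ip <- 0
  for (k in seq_along(xs)) ip <- ip + q$weights[k] * sum(geo$detJ * ex$pressure(xs[[k]]))
  expect_lt(abs(ip), 1e-12)
  # top-side WSS is the linear profile 60x; right side the constant (0, 20)
  xx <- cbind(seq(0, 1, 0.25), 1)
  expect_equal(ex$wss(xx, "top"), cbind(60 * xx[, 1], 0))
  expect_equal(ex$wss(xx, "right")[1, ], c(0, 20))
  expect_equal(ex$wss(xx, "left"), matrix(0, 5, 2))
})

test_that("the Poiseuille solution reproduces its closed-form quantities", {
  ex <- poiseuille_exact(R = 1e-3, u_m = 1, mu = 4e-3, rho = 1, L = 2e-3)
  expect_equal(ex$wss_magnitude, 8)
  # centreline and wall velocities
  expect_equal(ex$velocity(matrix(c(0, 0, 1e-3), 1))[3], 1)
  expect_equal(ex$velocity(matrix(c(1e-3, 0, 1e-3), 1))[3], 0)
  # flow rate pi R^2 u_m / 2 = pi R^2 vbar with vbar = 0.5
  expect_equal(ex$flow_rate, pi * 1e-6 * 0.5)
  expect_equal(ex$mean_velocity, 0.5)
  # numerically integrate v_z over a fine inlet disc triangulation
  cyl <- build_cylinder_mesh(1e-3, 2e-3, 1e-4)
  sel <- cyl$facet_tags == 1L
  f <- cyl$boundary_facets[sel, ]
  cen <- cyl$boundary_centroid[sel, ]
  qflow <- sum(cyl$boundary_measure[sel] * ex$velocity(cen)[, 3])
  expect_equal(qflow, ex$flow_rate, tolerance = 2e-3)
  expect_error(poiseuille_exact(R = -1), "positive")
})

test_that("l2_error is exact for represented fields and constant offsets", {
  m <- build_unit_square_mesh(5)
  sp <- fe_space(m, 2L)
  # quadratic field represented exactly in P2
  f <- function(x) cbind(x[, 1]^2 - x[, 2], 2 * x[, 1] * x[, 2])
  fh <- wssbench:::interpolate_nodal(sp, f)
  expect_lt(l2_error(fh, f), 1e-13)
  # constant offset c on the unit-measure domain gives error |c|
  g <- function(x) f(x) + matrix(rep(c(0.3, -0.4), each = nrow(x)), ncol = 2)
  expect_equal(l2_error(fh, g), sqrt(0.3^2 + 0.4^2), tolerance = 1e-12)
  # quadrature-degree robustness: a non-represented smooth field integrates
  # consistently across high degrees
  h <- function(x) cbind(sin(pi * x[, 1]), cos(pi * x[, 2]))
  e1 <- l2_error(fh, h, degree = 8)
  e2 <- l2_error(fh, h, degree = 12)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("rate fitting recovers power laws exactly and tolerates noise", {
  expect_equal(fit_convergence_rate(c(0.1, 0.05), c(1e-2, 2.5e-3)), 2,
               tolerance = 1e-12)
  h <- 2^-(1:5)
  expect_equal(fit_convergence_rate(h, 3.7 * h^2.31), 2.31, tolerance = 1e-12)
  set.seed(7)
  noisy <- 3.7 * h^2.31 * (1 + runif(5, -0.05, 0.05))
  expect_lt(abs(fit_convergence_rate(h, noisy) - 2.31), 0.1)
  expect_error(fit_convergence_rate(h, c(1, 1, 1, 1, -1)), "positive")
  expect_error(fit_convergence_rate(0.1, 0.01), "two")
})

# synthetic WSS field over the unit square boundary: dome = top, parent = bottom
square_wss_field <- function(n, dome_vals, parent_vals, degree = 0L) {
  m <- build_unit_square_mesh(n)
  sel <- which(m$facet_tags %in% c(3L, 4L))    # bottom, top
  nn <- if (degree == 0L) 1L else 2L
  fv <- array(0, c(length(sel), nn, 2))
  tags <- m$facet_tags[sel]
  vals <- numeric(length(sel))
  vals[tags == 4L] <- dome_vals
  vals[tags == 3L] <- parent_vals
  for (k in seq_len(nn)) fv[, k, 1] <- vals
  sol <- list(mesh = m)
  wssbench:::new_wss_field(sol, "projection", if (degree == 0L) "DG0" else "DG1",
                           sel, fv)
}

test_that("hemodynamic summary reproduces hand-computable LSA cases", {
  # uniform |tau| = 2 on the dome, parent mean 1: nothing below 0.1
  wf <- square_wss_field(10, dome_vals = rep(2, 10), parent_vals = rep(1, 10))
  hs <- hemodynamic_summary(wf, "top", "bottom")
  expect_equal(hs$parent_mean_wss, 1)
  expect_equal(hs$threshold, 0.1)
  expect_equal(hs$lsa, 0)
  expect_equal(hs$avg_wss, 2)
  expect_equal(hs$max_wss, 2); expect_equal(hs$min_wss, 2)

  # 10 equal-length facets, 2 below threshold: LSA = 20%
  dv <- rep(2, 10); dv[c(3, 7)] <- 0.05
  hs2 <- hemodynamic_summary(square_wss_field(10, dv, rep(1, 10)),
                             "top", "bottom")
  expect_equal(hs2$lsa, 20, tolerance = 1e-12)
  expect_true(hs2$min_wss <= hs2$avg_wss && hs2$avg_wss <= hs2$max_wss)

  # LSA is invariant under joint rescaling of the field
  dv3 <- seq(0.05, 2, length.out = 10)
  h_a <- hemodynamic_summary(square_wss_field(10, dv3, rep(1, 10)),
                             "top", "bottom")
  h_b <- hemodynamic_summary(square_wss_field(10, 7 * dv3, rep(7, 10)),
                             "top", "bottom")
  expect_equal(h_a$lsa, h_b$lsa, tolerance = 1e-12)

  expect_error(hemodynamic_summary(wf, "top", "top"), "disjoint")
  expect_error(hemodynamic_summary(wf, "left", "bottom"), "empty dome")
})

test_that("piecewise-linear LSA matches a per-quadrature-point area oracle", {
  # DG1 field straddling the threshold inside facets
  m <- build_unit_square_mesh(2)
  sel <- which(m$facet_tags %in% c(3L, 4L))
  fv <- array(0, c(length(sel), 2, 2))
  tags <- m$facet_tags[sel]
  fv[tags == 4L, 1, 1] <- c(0.02, 0.3)     # linear within each top facet
  fv[tags == 4L, 2, 1] <- c(0.3, 0.02)
  fv[tags == 3L, , 1] <- 1                 # parent: uniform 1
  wf <- wssbench:::new_wss_field(list(mesh = m), "projection", "DG1", sel, fv)
  hs <- hemodynamic_summary(wf, "top", "bottom")
  # oracle: same facet rule, thresholding |tau| at the quadrature points
  rule <- simplex_quadrature(1L, 2L)
  w <- wssbench:::facet_qweights(m, sel, rule)
  vals <- wssbench:::wss_at_qps(wf, rule)
  nq <- nrow(rule$points)
  dsel <- rep(tags == 4L, nq)
  mag <- abs(vals[, 1])
  lsa_oracle <- 100 * sum(as.vector(w)[dsel] * (mag[dsel] < hs$threshold)) /
    sum(as.vector(w)[dsel])
  expect_equal(hs$lsa, lsa_oracle, tolerance = 1e-12)
  expect_gt(hs$lsa, 0); expect_lt(hs$lsa, 100)
})

test_that("a Poiseuille solve feeds the full hemodynamic pipeline", {
  fx <- fixture("pois_p1p1", function() poiseuille_p1p1_solution())
  mesh2 <- split_region(fx$sol$mesh, "wall",
                        function(cen) cen[, 3] > 1e-3, "dome")
  # re-solve on the retagged mesh (tags changed, same geometry)
  bcs <- bc_spec(
    inlet = list(kind = "dirichlet_nitsche", value = fx$ex$velocity),
    wall = list(kind = "dirichlet_nitsche",
                value = function(x) matrix(0, nrow(x), 3)),
    dome = list(kind = "dirichlet_nitsche",
                value = function(x) matrix(0, nrow(x), 3)),
    outlet = list(kind = "zero_tangential_velocity"))
  sol <- solve_stokes(mesh2, fx$props, fx$cfg, bcs)
  wf <- project_wss(sol, c("wall", "dome"), "DG0")
  hs <- hemodynamic_summary(wf, "dome", "wall")
  # Poiseuille WSS is uniform (about 8 density-scaled): no low-shear area
  expect_equal(hs$avg_wss, 8, tolerance = 0.15)
  expect_equal(hs$parent_mean_wss, 8, tolerance = 0.15)
  expect_equal(hs$lsa, 0)
  expect_true(hs$min_wss <= hs$avg_wss && hs$avg_wss <= hs$max_wss)
})

test_that("convergence studies report monotone errors and stable rates", {
  s <- fixture("study_p1p1_small", function() {
    run_convergence_study("stokes2d", "P1P1_stabilized", levels = c(8, 16, 32),
                          wss_methods = "proj_dg0")
  })
  expect_true(all(diff(s$table$v) < 0))
  expect_true(all(diff(s$table$p) < 0))
  expect_true(all(diff(s$table$wss_proj_dg0) < 0))
  # dropping the coarsest level moves the fitted rate only slightly
  r_all <- s$rates[["v"]]
  r_fine <- fit_convergence_rate(s$table$h[-1], s$table$v[-1])
  expect_lt(abs(r_all - r_fine), 0.15)
  expect_error(run_convergence_study("stokes2d", "P1P1_stabilized",
                                     levels = 8), "two levels")
})
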
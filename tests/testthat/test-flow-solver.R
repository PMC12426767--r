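# Stokes/Navier-Stokes solver: null data, Nitsche and CIP oracles against
# hand-assembled quadrature, convergence behaviour, gauge fixing.

test_that("null data produce the zero solution", {
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
  expect_lt(max(abs(sol$v)), 1e-12)
  expect_lt(max(abs(sol$p)), 1e-10)
})

test_that("Nitsche boundary terms match a hand-assembled edge quadrature", {
  m <- one_triangle_mesh()
  sv <- fe_space(m, 1L)
  sp <- fe_space(m, 1L)
  geo <- wssbench:::cell_geometry(m)
  nu <- 0.7; beta <- 3
  vbc_fun <- function(x) cbind(0.2 + 0.1 * x[, 1], -0.3 * x[, 2])
  # bottom edge: facet with tag 3, vertices (0,0)-(1,0), n = (0,-1), h = sqrt(2)
  fs <- which(m$facet_tags == 3L)
  nit <- wssbench:::assemble_nitsche(sv, sp, fs, geo, nu, beta,
                                     "full_gradient", vbc_fun, 5L)
  # linear trial/test fields from nodal coefficients
  vcoef <- rbind(c(1, -2), c(0.5, 0.25), c(-1, 0.75))
  wcoef <- rbind(c(0.3, 1.2), c(-0.6, 0.1), c(0.9, -0.4))
  pcoef <- c(2, -1, 0.5)
  qcoef <- c(-0.7, 1.1, 0.4)
  vvec <- as.vector(t(vcoef)); wvec <- as.vector(t(wcoef))
  lhs_val <- sum(wvec * as.numeric(nit$VV %*% vvec)) +
    sum(wvec * as.numeric(nit$VP %*% pcoef)) +
    sum(qcoef * as.numeric(nit$QV %*% vvec))
  rhs_val <- sum(wvec * nit$rhs_v) + sum(qcoef * nit$rhs_p)

  # independent dense Gauss quadrature on the edge y = 0, t in [0,1]
  lam <- function(x) cbind(1 - x[, 1] - x[, 2], x[, 1], x[, 2])
  glam <- rbind(c(-1, -1), c(1, 0), c(0, 1))       # reference = physical here
  gq <- wssbench:::gauss_legendre_01(6)
  n_out <- c(0, -1)
  h <- m$cell_h[1]
  brute_bil <- 0; brute_rhs <- 0
  for (k in seq_along(gq$weights)) {
    x <- matrix(c(gq$points[k, 1], 0), 1)
    L <- lam(x)
    v <- as.vector(L %*% vcoef);  w <- as.vector(L %*% wcoef)
    p <- sum(L * pcoef);          q <- sum(L * qcoef)
    gradv <- t(glam) %*% vcoef    # [deriv, comp]
    gradw <- t(glam) %*% wcoef
    Tv_n <- nu * t(gradv) %*% n_out - p * n_out
    Tw_n <- nu * t(gradw) %*% n_out - q * n_out
    vbc <- as.vector(vbc_fun(x))
    brute_bil <- brute_bil + gq$weights[k] *
      (-sum(Tv_n * w) + sum(Tw_n * v) + beta * nu / h * sum(v * w))
    brute_rhs <- brute_rhs + gq$weights[k] *
      (sum(Tw_n * vbc) + beta * nu / h * sum(vbc * w))
  }
  expect_equal(lhs_val, brute_bil, tolerance = 1e-12)
  expect_equal(rhs_val, brute_rhs, tolerance = 1e-12)

  # consistency: v = v_bc on the boundary kills transpose and penalty terms
  vc <- vbc_fun(sv$nodes)
  vvec_bc <- as.vector(t(vc))
  resid <- as.numeric(nit$VV %*% vvec_bc) - nit$rhs_v
  # remaining term is -int (T(v,p)n).w with p = 0: compare to brute force
  brute <- numeric(6)
  for (k in seq_along(gq$weights)) {
    x <- matrix(c(gq$points[k, 1], 0), 1)
    L <- lam(x)
    gradv <- t(glam) %*% vc
    Tv_n <- nu * t(gradv) %*% n_out
    for (i in 1:3) for (a in 1:2) {
      brute[2 * (i - 1) + a] <- brute[2 * (i - 1) + a] -
        gq$weights[k] * Tv_n[a] * L[i]
    }
  }
  expect_equal(resid, brute, tolerance = 1e-12)
})

test_that("pure non-symmetric Nitsche (beta = 0) remains solvable", {
  ex <- stokes2d_exact()
  m <- build_unit_square_mesh(8)
  props <- fluid_properties(kinematic_viscosity = 1, density = 1,
                            density_scaled = TRUE)
  cfg <- discretization_config("P1P1_stabilized", "nitsche", beta = 0)
  sides <- c("left", "right", "bottom", "top")
  bcs <- do.call(bc_spec, stats::setNames(
    lapply(sides, function(s) list(kind = "dirichlet_nitsche",
                                   value = ex$velocity)), sides))
  sol <- solve_stokes(m, props, cfg, bcs)
  err <- l2_error(fe_function(sol$space_v, sol$v), ex$velocity)
  expect_lt(err, 0.2)   # coarse but convergent
})

test_that("CIP stabilization matches the hand-computed two-cell jump", {
  m <- two_triangle_mesh()
  sv <- fe_space(m, 1L)
  sp <- fe_space(m, 1L)
  geo <- wssbench:::cell_geometry(m)
  nu <- 1
  w <- stabilization_weights(gamma_p = 0.01, gamma_v = 0.02)
  cip <- wssbench:::assemble_cip(sv, sp, geo, w, nu)
  # piecewise-linear continuous p: nodal values; gradients differ per cell
  pcoef <- c(0, 1, 3, -2)
  qcoef <- c(1, -1, 2, 0.5)
  val <- sum(pcoef * as.numeric(cip$Sp %*% qcoef))
  # hand computation: cells (1,2,3) and (1,3,4); shared facet 1-3,
  # length sqrt(2), normal (1,-1)/sqrt(2)
  gradp <- function(tri, coef) {
    A <- cbind(1, m$vertices[tri, ])
    sol <- solve(A, coef[tri])
    sol[2:3]
  }
  nrm <- c(1, -1) / sqrt(2)
  jump_p <- sum(nrm * (gradp(c(1, 2, 3), pcoef) - gradp(c(1, 3, 4), pcoef)))
  jump_q <- sum(nrm * (gradp(c(1, 2, 3), qcoef) - gradp(c(1, 3, 4), qcoef)))
  h <- sqrt(2)                      # circumdiameter of both cells
  s <- ifelse(nu >= h, 2, 1)        # nu = 1 < sqrt(2): s = 1
  expect_identical(s, 1)
  wgt <- 0.5 * w$gamma_p * (h^(s + 1) + h^(s + 1)) * sqrt(2)
  expect_equal(val, wgt * jump_p * jump_q, tolerance = 1e-12)
  # globally linear p has no gradient jump
  plin <- 2 + 3 * m$vertices[, 1] - m$vertices[, 2]
  expect_lt(max(abs(cip$Sp %*% plin)), 1e-12)
})

test_that("the s-rule switches the CIP weight between h^3 and h^2", {
  m <- build_unit_square_mesh(4)
  sv <- fe_space(m, 1L); sp <- fe_space(m, 1L)
  geo <- wssbench:::cell_geometry(m)
  w <- stabilization_weights(gamma_p = 1, gamma_v = 0)
  h <- m$cell_h[1]                        # uniform
  cip_hi <- wssbench:::assemble_cip(sv, sp, geo, w, nu = 1)    # nu >= h: s=2
  cip_lo <- wssbench:::assemble_cip(sv, sp, geo, w, nu = 1e-9) # nu < h: s=1
  ratio <- cip_hi$Wp[1] / cip_lo$Wp[1]
  expect_equal(ratio, h, tolerance = 1e-12)
})

test_that("interior-penalty stabilization scales with the squared mesh size", {
  w <- stabilization_weights(alpha_v = 1e-3, alpha_p = 1, alpha_i = 1e-3)
  S_of <- function(scale) {
    verts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) * scale
    m <- tagged_mesh(verts, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
                     region_names = c("1" = "boundary"),
                     facet_tagger = function(cen, nrm) rep(1L, nrow(cen)))
    sv <- fe_space(m, 1L); sp <- fe_space(m, 1L)
    geo <- wssbench:::cell_geometry(m)
    st <- wssbench:::assemble_interior_penalty(sv, sp, geo, w)
    # gradient-jump-preserving fields: v2(x) = scale * v1(x / scale)
    vcoef <- cbind(c(0, 1, 3, -2), c(2, -1, 0, 1)) * scale
    vvec <- as.vector(t(vcoef))
    sum(vvec * as.numeric(st$Sv %*% vvec))
  }
  s1 <- S_of(1); s2 <- S_of(2)
  # jumps are preserved, so S scales as h^2 * facet measure = 4 * 2 in 2D
  expect_equal(s2 / s1, 8, tolerance = 1e-10)
  # globally linear fields are unpenalized
  m <- two_triangle_mesh()
  sv <- fe_space(m, 1L); sp <- fe_space(m, 1L)
  geo <- wssbench:::cell_geometry(m)
  st <- wssbench:::assemble_interior_penalty(sv, sp, geo, w)
  vlin <- cbind(1 + m$vertices[, 1], m$vertices[, 2] - 2 * m$vertices[, 1])
  expect_lt(max(abs(st$Sv %*% as.vector(t(vlin)))), 1e-12)
  plin <- 5 - m$vertices[, 1]
  expect_lt(max(abs(st$Sp %*% plin)), 1e-12)
})

test_that("Dirichlet-only solves return mean-zero pressure", {
  fx <- fixture("p1p1_n16", function() stokes2d_p1p1_solution(16))
  mv <- wssbench:::assemble_unit_load(fx$sol$space_p, fx$sol$geo)
  expect_lt(abs(sum(mv * fx$sol$p)), 1e-10)
  fx2 <- fixture("p2p1_n8", function() stokes2d_p2p1_solution(8))
  mv2 <- wssbench:::assemble_unit_load(fx2$sol$space_p, fx2$sol$geo)
  expect_lt(abs(sum(mv2 * fx2$sol$p)), 1e-10)
})

test_that("velocity divergence decreases under refinement for both pairs", {
  for (build in c("p1p1", "p2p1")) {
    divs <- sapply(c(8, 16), function(n) {
      fx <- fixture(paste0(build, "_n", n), function() {
        if (build == "p1p1") stokes2d_p1p1_solution(n) else
          stokes2d_p2p1_solution(n)
      })
      wssbench:::l2_div_norm(fe_function(fx$sol$space_v, fx$sol$v))
    })
    expect_lt(divs[2], divs[1])
  }
})

test_that("strong and Nitsche enforcement agree increasingly under refinement", {
  ex <- stokes2d_exact()
  props <- fluid_properties(kinematic_viscosity = 1, density = 1,
                            density_scaled = TRUE)
  sides <- c("left", "right", "bottom", "top")
  dists <- sapply(c(8, 16), function(n) {
    m <- build_unit_square_mesh(n)
    cfg_s <- discretization_config("P2P1", "strong")
    cfg_n <- discretization_config("P2P1", "nitsche", beta = 10)
    bc <- function(kind) do.call(bc_spec, stats::setNames(
      lapply(sides, function(s) list(kind = kind, value = ex$velocity)),
      sides))
    sol_s <- solve_stokes(m, props, cfg_s, bc("dirichlet_strong"))
    sol_n <- solve_stokes(m, props, cfg_n, bc("dirichlet_nitsche"))
    sqrt(sum((sol_s$v - sol_n$v)^2) / nrow(sol_s$v))
  })
  expect_lt(dists[2], dists[1])
})

test_that("steady Navier-Stokes matches Stokes in the creeping-flow limit", {
  ex <- poiseuille_exact()
  p <- ex$params
  props <- fluid_properties(kinematic_viscosity = p$nu, density = 1,
                            density_scaled = TRUE)
  cfg <- discretization_config("P1P1_stabilized", "nitsche", beta = 10,
                               stress_form = "symmetric",
                               stabilization = stabilization_weights(
                                 gamma_p = 1, gamma_v = 1e-3),
                               cip_style = "interior_penalty")
  bcs <- bc_spec(
    inlet = list(kind = "dirichlet_nitsche", value = ex$velocity),
    wall = list(kind = "dirichlet_nitsche",
                value = function(x) matrix(0, nrow(x), 3)),
    outlet = list(kind = "zero_tangential_velocity"))
  mesh <- build_cylinder_mesh(p$R, p$L, p$R / 2.5)
  ns <- solve_navier_stokes_steady(mesh, props, cfg, bcs)
  expect_true(ns$steady)
  # terminal time-derivative norm below the steady tolerance
  expect_lt(utils::tail(ns$history$dudt, 1), 1e-5)
  # dt respects the configured bounds
  expect_true(all(ns$history$dt >= 1e-2 - 1e-12))
  expect_true(all(ns$history$dt <= 1e5 + 1e-12))
  # at this Reynolds number (convection negligible at steady Poiseuille) the
  # steady NS state reproduces the parabolic profile like the Stokes solve
  cfg_st <- discretization_config("P1P1_stabilized", "nitsche", beta = 10,
                                  stress_form = "symmetric",
                                  stabilization = stabilization_weights(
                                    gamma_p = 1, gamma_v = 1e-3))
  st <- solve_stokes(mesh, props, cfg_st, bcs)
  e_ns <- l2_error(fe_function(ns$space_v, ns$v), ex$velocity)
  e_st <- l2_error(fe_function(st$space_v, st$v), ex$velocity)
  expect_lt(e_ns, 2 * e_st + 1e-12)
})

test_that("mismatched enforcement configuration is rejected", {
  ex <- stokes2d_exact()
  m <- build_unit_square_mesh(4)
  props <- fluid_properties(kinematic_viscosity = 1, density = 1,
                            density_scaled = TRUE)
  cfg <- discretization_config("P2P1", "strong")
  bcs <- bc_spec(left = list(kind = "dirichlet_nitsche", value = ex$velocity),
                 right = list(kind = "dirichlet_strong", value = ex$velocity),
                 bottom = list(kind = "dirichlet_strong", value = ex$velocity),
                 top = list(kind = "dirichlet_strong", value = ex$velocity))
  expect_error(solve_stokes(m, props, cfg, bcs), "enforcement is strong")
})
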
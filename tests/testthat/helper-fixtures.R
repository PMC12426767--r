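# Shared fixtures: tiny meshes, benchmark solutions cached across test files
# (each is computed once per test run).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# one-triangle mesh of the reference triangle, side tags 1..3
one_triangle_mesh <- function() {
  tagged_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)),
              rbind(c(1L, 2L, 3L)),
              region_names = c("1" = "hyp", "2" = "left", "3" = "bottom"),
              facet_tagger = function(cen, nrm) {
                ifelse(cen[, 1] < 1e-12, 2L,
                       ifelse(cen[, 2] < 1e-12, 3L, 1L))
              })
}

# two right triangles sharing the diagonal of the unit square
two_triangle_mesh <- function() {
  tagged_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
              rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
              region_names = c("1" = "boundary"),
              facet_tagger = function(cen, nrm) rep(1L, nrow(cen)))
}

# one-tetrahedron mesh
one_tet_mesh <- function() {
  tagged_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
              rbind(c(1L, 2L, 3L, 4L)),
              region_names = c("1" = "boundary"),
              facet_tagger = function(cen, nrm) rep(1L, nrow(cen)))
}

# build a flow_solution directly from prescribed polynomial fields
manufactured_solution <- function(mesh, vfun, pfun, nu = 1,
                                  stress_form = "full_gradient", degree = 1L) {
  space_v <- fe_space(mesh, degree)
  space_p <- fe_space(mesh, 1L)
  structure(list(
    mesh = mesh, space_v = space_v, space_p = space_p,
    v = as.matrix(vfun(space_v$nodes)), p = as.numeric(pfun(space_p$nodes)),
    props = fluid_properties(kinematic_viscosity = nu, density = 1,
                             density_scaled = TRUE),
    config = discretization_config("P2P1", "strong",
                                   stress_form = stress_form),
    bcs = bc_spec(f = NULL), stab = NULL,
    geo = wssbench:::cell_geometry(mesh), gauge = FALSE,
    nitsche_facets = integer(0), qdeg_facet = 2L * degree + 1L,
    problem = "stokes", dudt = NULL, ip_vn2 = NULL
  ), class = "flow_solution")
}

# Dense-quadrature oracle for the boundary-flux right-hand side on the
# reference triangle with v = (1 + 2x - y, 0.5x + y), p = 2 - x + 3y,
# wall = bottom edge, Neumann subtraction on the other two edges.
bflux_one_cell_oracle <- function(m, nu) {
  verts <- m$vertices
  lam_coef <- solve(cbind(1, verts))
  G <- rbind(c(2, 0.5), c(-1, 1))        # [deriv, comp]
  gradlam <- lam_coef[2:3, ]
  tq <- wssbench:::simplex_quadrature(2L, 8L)
  oracle <- numeric(6)
  for (k in seq_along(tq$weights)) {
    x <- tq$points[k, , drop = FALSE]
    pval <- 2 - x[1] + 3 * x[2]
    w2 <- tq$weights[k]
    for (i in 1:3) for (a in 1:2) {
      val <- nu * sum(G[, a] * gradlam[, i]) - pval * gradlam[a, i]
      oracle[2 * (i - 1) + a] <- oracle[2 * (i - 1) + a] + w2 * val
    }
  }
  edges <- list(list(a = 1, b = 2, n = c(0, -1), wall = TRUE),
                list(a = 2, b = 3, n = c(1, 1) / sqrt(2), wall = FALSE),
                list(a = 3, b = 1, n = c(-1, 0), wall = FALSE))
  gq <- wssbench:::gauss_legendre_01(6)
  for (e in edges) {
    pa <- verts[e$a, ]; pb <- verts[e$b, ]
    len <- sqrt(sum((pb - pa)^2))
    for (k in seq_along(gq$weights)) {
      x <- (1 - gq$points[k, 1]) * pa + gq$points[k, 1] * pb
      lam <- as.vector(c(1, x) %*% lam_coef)
      pval <- 2 - x[1] + 3 * x[2]
      tn <- nu * as.vector(t(G) %*% e$n) - pval * e$n
      wq <- gq$weights[k] * len
      for (i in 1:3) for (a in 1:2) {
        sub <- if (e$wall) sum(tn * e$n) * e$n[a] else tn[a]
        oracle[2 * (i - 1) + a] <- oracle[2 * (i - 1) + a] - wq * sub * lam[i]
      }
    }
  }
  oracle
}

# small stabilized P1/P1 solve of the manufactured 2D Stokes problem
stokes2d_p1p1_solution <- function(n = 16) {
  ex <- stokes2d_exact()
  props <- fluid_properties(kinematic_viscosity = 1, density = 1,
                            density_scaled = TRUE)
  cfg <- discretization_config("P1P1_stabilized", "nitsche", beta = 10,
                               stress_form = "full_gradient",
                               stabilization = stabilization_weights(
                                 gamma_p = 1e-2, gamma_v = 1e-2))
  sides <- c("left", "right", "bottom", "top")
  bcs <- do.call(bc_spec, stats::setNames(
    lapply(sides, function(s) list(kind = "dirichlet_nitsche",
                                   value = ex$velocity)), sides))
  list(sol = solve_stokes(build_unit_square_mesh(n), props, cfg, bcs),
       ex = ex, bcs = bcs, props = props, cfg = cfg)
}

# small Taylor-Hood solve of the same problem with strong BCs
stokes2d_p2p1_solution <- function(n = 8) {
  ex <- stokes2d_exact()
  props <- fluid_properties(kinematic_viscosity = 1, density = 1,
                            density_scaled = TRUE)
  cfg <- discretization_config("P2P1", "strong", stress_form = "full_gradient")
  sides <- c("left", "right", "bottom", "top")
  bcs <- do.call(bc_spec, stats::setNames(
    lapply(sides, function(s) list(kind = "dirichlet_strong",
                                   value = ex$velocity)), sides))
  list(sol = solve_stokes(build_unit_square_mesh(n), props, cfg, bcs),
       ex = ex, bcs = bcs, props = props, cfg = cfg)
}

# coarse Poiseuille P1/P1 solve (paper boundary conditions)
poiseuille_p1p1_solution <- function(edge = 1e-3 / 3) {
  ex <- poiseuille_exact()
  p <- ex$params
  props <- fluid_properties(kinematic_viscosity = p$nu, density = 1,
                            density_scaled = TRUE)
  cfg <- discretization_config("P1P1_stabilized", "nitsche", beta = 10,
                               stress_form = "symmetric",
                               stabilization = stabilization_weights(
                                 gamma_p = 1, gamma_v = 1e-3))
  bcs <- bc_spec(
    inlet = list(kind = "dirichlet_nitsche", value = ex$velocity),
    wall = list(kind = "dirichlet_nitsche",
                value = function(x) matrix(0, nrow(x), 3)),
    outlet = list(kind = "zero_tangential_velocity"))
  mesh <- build_cylinder_mesh(p$R, p$L, edge)
  list(sol = solve_stokes(mesh, props, cfg, bcs), ex = ex, props = props,
       cfg = cfg, bcs = bcs)
}

# all-Dirichlet (Nitsche) Poiseuille variant: the configuration in which the
# boundary-flux and projection recoveries coincide algebraically
poiseuille_all_dirichlet_solution <- function(edge = 1e-3 / 3) {
  ex <- poiseuille_exact()
  p <- ex$params
  props <- fluid_properties(kinematic_viscosity = p$nu, density = 1,
                            density_scaled = TRUE)
  cfg <- discretization_config("P1P1_stabilized", "nitsche", beta = 10,
                               stress_form = "symmetric",
                               stabilization = stabilization_weights(
                                 gamma_p = 1, gamma_v = 1e-3))
  bcs <- bc_spec(
    inlet = list(kind = "dirichlet_nitsche", value = ex$velocity),
    wall = list(kind = "dirichlet_nitsche",
                value = function(x) matrix(0, nrow(x), 3)),
    outlet = list(kind = "dirichlet_nitsche", value = ex$velocity))
  mesh <- build_cylinder_mesh(p$R, p$L, edge)
  list(sol = solve_stokes(mesh, props, cfg, bcs), ex = ex, props = props,
       cfg = cfg, bcs = bcs)
}
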
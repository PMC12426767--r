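# Convergence-study orchestration for the two analytic benchmarks, mirroring
# the structure of the published mesh-refinement experiments: per level,
# build the mesh, solve, measure L2 errors of velocity, pressure and every
# requested WSS method, then fit log-log rates.

#' Benchmark problem setup (mesh builder, solver configs, exact fields)
#'
#' @param problem "stokes2d" or "poiseuille".
#' @param element_pair "P1P1_stabilized" or "P2P1".
#' @param mesh_family "uniform" or "boundary_layer" (cylinder only).
#' @param beta Nitsche penalty for the P1/P1 pair.
#' @keywords internal
benchmark_setup <- function(problem, element_pair, mesh_family = "uniform",
                            beta = 10) {
  if (problem == "stokes2d") {
    ex <- stokes2d_exact()
    props <- fluid_properties(kinematic_viscosity = 1, density = 1,
                              density_scaled = TRUE)
    if (element_pair == "P1P1_stabilized") {
      cfg <- discretization_config("P1P1_stabilized", "nitsche", beta = beta,
                                   stress_form = "full_gradient",
                                   stabilization = stabilization_weights(
                                     gamma_p = 1e-2, gamma_v = 1e-2))
      kind <- "dirichlet_nitsche"
    } else {
      cfg <- discretization_config("P2P1", "strong",
                                   stress_form = "full_gradient")
      kind <- "dirichlet_strong"
    }
    sides <- c("left", "right", "bottom", "top")
    bcs <- do.call(bc_spec, stats::setNames(
      lapply(sides, function(s) list(kind = kind, value = ex$velocity)), sides))
    list(exact = ex, props = props, config = cfg, bcs = bcs,
         mesh_fun = function(res) build_unit_square_mesh(res),
         h_fun = function(res) 1 / res,
         wall_tags = sides, segmented = TRUE)
  } else if (problem == "poiseuille") {
    ex <- poiseuille_exact()
    p <- ex$params
    props <- fluid_properties(kinematic_viscosity = p$nu, density = 1,
                              density_scaled = TRUE)
    if (element_pair == "P1P1_stabilized") {
      cfg <- discretization_config("P1P1_stabilized", "nitsche", beta = beta,
                                   stress_form = "symmetric",
                                   stabilization = stabilization_weights(
                                     gamma_p = 1, gamma_v = 1e-3))
      kind <- "dirichlet_nitsche"
    } else {
      cfg <- discretization_config("P2P1", "strong", stress_form = "symmetric")
      kind <- "dirichlet_strong"
    }
    inflow <- function(x) ex$velocity(x)
    noslip <- function(x) matrix(0, nrow(x), 3)
    bcs <- bc_spec(
      inlet = list(kind = kind, value = inflow),
      wall = list(kind = kind, value = noslip),
      outlet = list(kind = "zero_tangential_velocity")
    )
    bl <- if (mesh_family == "boundary_layer") boundary_layer_spec() else NULL
    list(exact = ex, props = props, config = cfg, bcs = bcs,
         mesh_fun = function(res) build_cylinder_mesh(p$R, p$L, res, bl),
         h_fun = function(res) res,
         wall_tags = "wall", segmented = FALSE)
  } else stop("unknown problem '", problem, "'")
}

# compute one WSS field by canonical method name
compute_wss <- function(sol, setup, method) {
  wall <- setup$wall_tags
  seg <- setup$segmented
  switch(method,
    bflux_p1 = if (seg) wss_per_segment(sol, wall, "boundary_flux", "P1")
               else boundary_flux_wss(sol, wall, "P1"),
    bflux_p2 = if (seg) wss_per_segment(sol, wall, "boundary_flux", "P2")
               else boundary_flux_wss(sol, wall, "P2"),
    proj_p1 = if (seg) wss_per_segment(sol, wall, "projection", "P1")
              else project_wss(sol, wall, "P1"),
    proj_dg1 = project_wss(sol, wall, "DG1"),
    proj_dg0 = project_wss(sol, wall, "DG0"),
    stop("unknown WSS method '", method, "'")
  )
}

#' Run a mesh-convergence study on an analytic benchmark
#'
#' For each resolution: builds the mesh, solves the Stokes problem with the
#' chosen element pair, measures L2 errors of velocity, pressure and each
#' requested WSS recovery method against the closed-form solution, and fits
#' log-log convergence rates.
#'
#' @param problem "stokes2d" (unit square, manufactured solution) or
#'   "poiseuille" (cylinder).
#' @param element_pair "P1P1_stabilized" or "P2P1".
#' @param levels resolutions: elements per side (stokes2d) or edge lengths in
#'   metres (poiseuille); at least two.
#' @param wss_methods subset of c("bflux_p1", "bflux_p2", "proj_p1",
#'   "proj_dg1", "proj_dg0").
#' @param mesh_family "uniform" or "boundary_layer" (cylinder only).
#' @param beta Nitsche penalty parameter for P1/P1 runs.
#' @param verbose print per-level progress.
#' @return a `convergence_study`: data frame of levels/errors plus fitted
#'   rates and metadata.
#' @export
run_convergence_study <- function(problem = c("stokes2d", "poiseuille"),
                                  element_pair = c("P2P1", "P1P1_stabilized"),
                                  levels,
                                  wss_methods = c("bflux_p1", "proj_p1",
                                                  "proj_dg1", "proj_dg0"),
                                  mesh_family = "uniform", beta = 10,
                                  verbose = FALSE) {
  problem <- match.arg(problem)
  element_pair <- match.arg(element_pair)
  if (length(levels) < 2L) stop("need at least two levels")
  if (element_pair == "P1P1_stabilized" && "bflux_p2" %in% wss_methods) {
    stop("boundary-flux space P2 exceeds the P1 velocity degree")
  }
  setup <- benchmark_setup(problem, element_pair, mesh_family, beta)
  ex <- setup$exact
  rows <- list()
  for (li in seq_along(levels)) {
    res <- levels[li]
    t0 <- Sys.time()
    mesh <- setup$mesh_fun(res)
    sol <- solve_stokes(mesh, setup$props, setup$config, setup$bcs)
    errs <- c(
      v = l2_error(fe_function(sol$space_v, sol$v), ex$velocity,
                   degree = 2L * sol$space_v$degree + ex$poly_degree),
      p = l2_error(fe_function(sol$space_p, sol$p), ex$pressure,
                   degree = 2L + ex$poly_degree)
    )
    exw <- function(x, side) ex$wss(x, side)
    for (mth in wss_methods) {
      wf <- compute_wss(sol, setup, mth)
      errs[[paste0("wss_", mth)]] <- l2_error_wss(wf, exw)
      errs[[paste0("mag_", mth)]] <- wss_summary_stats(wf)$avg
    }
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    rows[[li]] <- data.frame(level = res, h = setup$h_fun(res),
                             h_max = max(mesh$cell_h),
                             n_cells = nrow(mesh$cells),
                             as.list(errs), seconds = dt,
                             check.names = FALSE)
    if (verbose) {
      message(sprintf("[%s %s %s] level %g: %d cells, err_v=%.3e err_p=%.3e (%.1fs)",
                      problem, element_pair, mesh_family, res,
                      nrow(mesh$cells), errs[["v"]], errs[["p"]], dt))
    }
  }
  tab <- do.call(rbind, rows)
  qty <- grep("^(v$|p$|wss_)", names(tab), value = TRUE)
  rates <- vapply(qty, function(qn) fit_convergence_rate(tab$h, tab[[qn]]),
                  numeric(1))
  structure(list(problem = problem, element_pair = element_pair,
                 mesh_family = mesh_family, wss_methods = wss_methods,
                 table = tab, rates = rates, beta = beta),
            class = "convergence_study")
}

#' Canonical resolution sets of the benchmark suite
#'
#' The mesh-refinement levels used by the packaged convergence studies:
#' elements per side for the unit square, target edge lengths (m) for the
#' cylinder.  These sizes keep every study within a few minutes on one CPU
#' while staying inside the asymptotic regime the fitted rates require.
#'
#' @return named list of numeric vectors.
#' @export
benchmark_suite_levels <- function() {
  list(
    stokes2d_p1p1 = c(8, 16, 32, 64, 128),
    stokes2d_p2p1 = c(8, 16, 32, 64, 128),
    poiseuille_p1p1 = 1e-3 / c(3, 4, 6, 8),
    poiseuille_p2p1 = 1e-3 / c(3, 4, 6),
    poiseuille_p2p1_bl = 1e-3 / c(3, 4, 5)
  )
}

#' @export
print.convergence_study <- function(x, ...) {
  cat(sprintf("<convergence_study> %s, %s, %s meshes (%d levels)\n",
              x$problem, x$element_pair, x$mesh_family, nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 4)
  cat("fitted rates:\n")
  print(round(x$rates, 3))
  invisible(x)
}
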
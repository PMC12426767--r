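# Configuration value types: fluid properties, stabilization weights,
# discretization choices and boundary-condition specifications.

#' Fluid properties
#'
#' @param dynamic_viscosity mu (Pa s).
#' @param density rho (kg/m^3).
#' @param kinematic_viscosity nu (m^2/s); derived if missing.
#' @param density_scaled if TRUE the momentum equation is divided by density
#'   (rho = 1, nu acts as the momentum coefficient), as in the analytic
#'   benchmarks where pressure and WSS are reported density-scaled.
#' @export
fluid_properties <- function(dynamic_viscosity = NULL, density = 1,
                             kinematic_viscosity = NULL,
                             density_scaled = FALSE) {
  if (is.null(kinematic_viscosity) && is.null(dynamic_viscosity)) {
    stop("give dynamic_viscosity or kinematic_viscosity")
  }
  if (is.null(kinematic_viscosity)) {
    kinematic_viscosity <- dynamic_viscosity / density
  }
  if (is.null(dynamic_viscosity)) {
    dynamic_viscosity <- kinematic_viscosity * density
  }
  if (abs(dynamic_viscosity - density * kinematic_viscosity) >
      1e-12 * max(abs(dynamic_viscosity), 1e-300)) {
    stop("inconsistent properties: mu != rho * nu")
  }
  if (any(c(dynamic_viscosity, density, kinematic_viscosity) <= 0)) {
    stop("fluid properties must be positive")
  }
  if (density_scaled) {
    density <- 1
    dynamic_viscosity <- kinematic_viscosity
  }
  structure(list(mu = dynamic_viscosity, nu = kinematic_viscosity,
                 rho = density, density_scaled = density_scaled),
            class = "fluid_properties")
}

#' Stabilization weights
#'
#' `gamma_p`, `gamma_v` drive the continuous interior-penalty (CIP)
#' stabilization of the equal-order P1/P1 pair (jumps of the pressure normal
#' gradient and of the velocity divergence, scaled by h_K^(s+1) with s = 2
#' where nu >= h_K and s = 1 otherwise).  `alpha_i`, `alpha_v`, `alpha_p`
#' drive the h^2-scaled interior-penalty stabilization used for Navier-Stokes
#' runs.
#' @export
stabilization_weights <- function(gamma_p = 1e-2, gamma_v = 1e-2,
                                  alpha_i = 1e-3, alpha_v = 1e-3,
                                  alpha_p = 1) {
  w <- list(gamma_p = gamma_p, gamma_v = gamma_v,
            alpha_i = alpha_i, alpha_v = alpha_v, alpha_p = alpha_p)
  if (any(unlist(w) < 0)) stop("stabilization weights must be >= 0")
  structure(w, class = "stabilization_weights")
}

#' Discretization configuration
#'
#' @param element_pair "P1P1_stabilized" or "P2P1".
#' @param enforcement "strong" or "nitsche" (non-symmetric, penalty `beta`).
#' @param beta Nitsche penalty scale (beta * nu / h); 0 gives the pure
#'   non-symmetric method, which remains well-posed.
#' @param stress_form "full_gradient" (T = -pI + nu grad v) or "symmetric"
#'   (T = -pI + 2 nu D(v)).
#' @param stabilization a [stabilization_weights()].
#' @param cip_style "cip" (gamma-weighted jumps, Stokes) or
#'   "interior_penalty" (alpha-weighted, Navier-Stokes).
#' @param pseudo_time list of BDF2 pseudo-time-marching controls for steady
#'   Navier-Stokes: dt bounds, inflow ramp duration, end time and the
#'   steady-state tolerance on the time-derivative norm.
#' @export
discretization_config <- function(element_pair = c("P2P1", "P1P1_stabilized"),
                                  enforcement = c("strong", "nitsche"),
                                  beta = 10,
                                  stress_form = c("full_gradient", "symmetric"),
                                  stabilization = stabilization_weights(),
                                  cip_style = c("cip", "interior_penalty"),
                                  pseudo_time = list()) {
  element_pair <- match.arg(element_pair)
  enforcement <- match.arg(enforcement)
  stress_form <- match.arg(stress_form)
  cip_style <- match.arg(cip_style)
  if (beta < 0) stop("nitsche beta must be >= 0")
  if (element_pair == "P1P1_stabilized") {
    on <- if (cip_style == "cip") {
      stabilization$gamma_p > 0
    } else {
      stabilization$alpha_p > 0
    }
    if (!on) stop("P1P1_stabilized requires nonzero pressure stabilization")
  }
  pt <- utils::modifyList(list(scheme = "BDF2", dt_min = 1e-2, dt_max = 1e5,
                               ramp_duration = 0.5, end_time = 1e6,
                               steady_tol = 1e-5), pseudo_time)
  structure(list(element_pair = element_pair, enforcement = enforcement,
                 beta = beta, stress_form = stress_form,
                 stabilization = stabilization, cip_style = cip_style,
                 pseudo_time = pt),
            class = "discretization_config")
}

#' Boundary-condition specification
#'
#' One entry per tagged boundary region.  Kinds: `dirichlet_strong`,
#' `dirichlet_nitsche` (value = function(x) -> n x dim matrix),
#' `traction` (value = traction function g), `do_nothing`, and
#' `zero_tangential_velocity` (strong zero on the in-plane components of an
#' axis-aligned outlet, natural condition on the normal component).
#'
#' @param ... named arguments `<region label or id> = list(kind=, value=)`,
#'   or just `kind` as a string for kinds without a value.
#' @param f optional body-force function(x) -> n x dim matrix.
#' @export
bc_spec <- function(..., f = NULL) {
  regions <- list(...)
  regions <- lapply(regions, function(r) {
    if (is.character(r)) r <- list(kind = r)
    stopifnot(r$kind %in% c("dirichlet_strong", "dirichlet_nitsche",
                            "traction", "do_nothing",
                            "zero_tangential_velocity"))
    r
  })
  structure(list(regions = regions, f = f), class = "bc_spec")
}

element_degree <- function(element_pair) {
  if (element_pair == "P2P1") 2L else 1L
}
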
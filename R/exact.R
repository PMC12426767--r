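# Closed-form benchmark solutions: the 2D Stokes manufactured solution on the
# unit square and Poiseuille flow in a cylinder, with exact wall shear stress
# per tagged boundary segment.  Both are verified at construction time by
# evaluating the (polynomial) divergence and momentum residuals on a dense
# grid with more points per direction than the polynomial degree, which makes
# the check a polynomial-identity test.

#' Manufactured 2D Stokes solution on the unit square
#'
#' Velocity `v = (20 x y^3, 5 x^4 - 5 y^4)`, pressure
#' `p = 60 x^2 y - 20 y^3 - 5` (zero mean), kinematic viscosity 1, zero body
#' force, full-gradient stress `T = -p I + grad v`.  The exact WSS vanishes
#' on the left and bottom sides, is the constant `(0, 20)` on the right side
#' and `(60 x, 0)` on the top, with a jump at the upper-right corner.
#'
#' @return an `exact_solution` with fields `velocity`, `pressure`,
#'   `vel_grad`, `wss(x, side)` and `params`.
#' @export
stokes2d_exact <- function() {
  velocity <- function(x) cbind(20 * x[, 1] * x[, 2]^3,
                                5 * x[, 1]^4 - 5 * x[, 2]^4)
  pressure <- function(x) 60 * x[, 1]^2 * x[, 2] - 20 * x[, 2]^3 - 5
  vel_grad <- function(x) {  # [pt, comp a, deriv b]
    n <- nrow(x)
    g <- array(0, c(n, 2, 2))
    g[, 1, 1] <- 20 * x[, 2]^3
    g[, 1, 2] <- 60 * x[, 1] * x[, 2]^2
    g[, 2, 1] <- 20 * x[, 1]^3
    g[, 2, 2] <- -20 * x[, 2]^3
    g
  }
  wss <- function(x, side) {
    n <- nrow(x)
    switch(side,
           left = matrix(0, n, 2),
           bottom = matrix(0, n, 2),
           right = cbind(rep(0, n), rep(20, n)),
           top = cbind(60 * x[, 1], rep(0, n)),
           stop("unknown side '", side, "'"))
  }
  ex <- structure(list(
    name = "stokes2d", dim = 2L,
    velocity = velocity, pressure = pressure, vel_grad = vel_grad,
    wss = wss, poly_degree = 4L,
    params = list(nu = 1, stress_form = "full_gradient", f = NULL)
  ), class = "exact_solution")
  verify_exact_stokes2d(ex)
  ex
}

# polynomial-identity residual check on a dense tensor grid
verify_exact_stokes2d <- function(ex, tol = 1e-10) {
  g <- seq(0, 1, length.out = 8)   # > poly degree + 1 points per direction
  x <- as.matrix(expand.grid(g, g))
  # divergence via exact gradient
  gr <- ex$vel_grad(x)
  divv <- gr[, 1, 1] + gr[, 2, 2]
  if (max(abs(divv)) > tol) stop("exact solution violates div v = 0")
  # momentum: nu lap v - grad p = 0 (f = 0).  Richardson-extrapolated central
  # differences are exact (to roundoff) for quartic polynomials.
  lap1 <- function(f, x, eps) {
    out <- 0
    for (d in 1:2) {
      xp <- x; xm <- x
      xp[, d] <- xp[, d] + eps; xm[, d] <- xm[, d] - eps
      out <- out + (f(xp) - 2 * f(x) + f(xm)) / eps^2
    }
    out
  }
  lap <- function(f, x, eps = 1e-2) (4 * lap1(f, x, eps) - lap1(f, x, 2 * eps)) / 3
  gradp <- function(x, d, eps = 1e-2) {
    xp <- x; xm <- x; xP <- x; xM <- x
    xp[, d] <- xp[, d] + eps; xm[, d] <- xm[, d] - eps
    xP[, d] <- xP[, d] + 2 * eps; xM[, d] <- xM[, d] - 2 * eps
    (8 * (ex$pressure(xp) - ex$pressure(xm)) -
       (ex$pressure(xP) - ex$pressure(xM))) / (12 * eps)
  }
  r1 <- lap(function(y) ex$velocity(y)[, 1], x) - gradp(x, 1)
  r2 <- lap(function(y) ex$velocity(y)[, 2], x) - gradp(x, 2)
  if (max(abs(c(r1, r2))) > 1e-8) {
    stop("exact solution violates the Stokes momentum equation")
  }
  invisible(TRUE)
}

#' Poiseuille flow in a cylinder
#'
#' Axial velocity `v_z = u_m (1 - r^2/R^2)` in a cylinder of radius `R`
#' aligned with z over `[0, L]`; wall WSS magnitude `2 mu u_m / R` directed
#' along -z.  With `density_scaled = TRUE` stresses are divided by density
#' (momentum coefficient nu), matching how the benchmark reports pressure
#' and WSS.
#'
#' @param R radius (m). @param u_m centreline velocity (m/s).
#' @param mu dynamic viscosity (Pa s). @param rho density (kg/m^3).
#' @param L cylinder length (m).
#' @param density_scaled report density-scaled stresses (default TRUE).
#' @export
poiseuille_exact <- function(R = 1e-3, u_m = 1, mu = 4e-3, rho = 1,
                             L = 2e-3, density_scaled = TRUE) {
  if (!(R > 0 && u_m > 0 && mu > 0 && rho > 0 && L > 0)) {
    stop("R, u_m, mu, rho, L must be positive")
  }
  nu <- mu / rho
  coef <- if (density_scaled) nu else mu
  velocity <- function(x) {
    r2 <- x[, 1]^2 + x[, 2]^2
    cbind(0 * r2, 0 * r2, u_m * pmax(0, 1 - r2 / R^2))
  }
  pressure <- function(x) 4 * coef * u_m * (L - x[, 3]) / R^2
  vel_grad <- function(x) {
    n <- nrow(x)
    g <- array(0, c(n, 3, 3))
    g[, 3, 1] <- -2 * u_m * x[, 1] / R^2
    g[, 3, 2] <- -2 * u_m * x[, 2] / R^2
    g
  }
  tau_w <- 2 * coef * u_m / R
  wss <- function(x, side = "wall") {
    n <- nrow(x)
    cbind(rep(0, n), rep(0, n), rep(-tau_w, n))
  }
  ex <- structure(list(
    name = "poiseuille", dim = 3L,
    velocity = velocity, pressure = pressure, vel_grad = vel_grad,
    wss = wss, poly_degree = 2L,
    wss_magnitude = tau_w,
    mean_velocity = u_m / 2,
    flow_rate = pi * R^2 * u_m / 2,
    params = list(R = R, u_m = u_m, mu = mu, rho = rho, nu = nu, L = L,
                  density_scaled = density_scaled,
                  stress_form = "symmetric", f = NULL)
  ), class = "exact_solution")
  verify_exact_poiseuille(ex)
  ex
}

verify_exact_poiseuille <- function(ex, tol = 1e-9) {
  p <- ex$params
  # sample points including the wall and axis
  r <- seq(0, p$R, length.out = 5)
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  z <- seq(0, p$L, length.out = 4)
  g <- expand.grid(r = r, th = th, z = z)
  x <- cbind(g$r * cos(g$th), g$r * sin(g$th), g$z)
  gr <- ex$vel_grad(x)
  divv <- gr[, 1, 1] + gr[, 2, 2] + gr[, 3, 3]
  if (max(abs(divv)) > tol) stop("Poiseuille solution violates div v = 0")
  # momentum (density-scaled): nu lap v_z = dp/dz; both closed-form constants
  lap_vz <- -4 * p$u_m / p$R^2                  # exact Laplacian of v_z
  coef <- if (p$density_scaled) p$nu else p$mu
  dpdz <- -4 * coef * p$u_m / p$R^2
  if (abs(coef * lap_vz - dpdz) > tol * abs(dpdz)) {
    stop("Poiseuille solution violates the momentum balance")
  }
  # do-nothing outlet: T n has zero tangential part and -p(L) = 0 normal part
  if (abs(ex$pressure(matrix(c(0, 0, p$L), 1))) > tol) {
    stop("Poiseuille pressure does not satisfy the outlet condition")
  }
  invisible(TRUE)
}
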
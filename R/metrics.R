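# Error norms and convergence-rate fitting.

# physical coordinates of the volume quadrature points, per rule point
vol_qpoints <- function(mesh, quad) {
  d <- mesh$dim
  lapply(seq_len(nrow(quad$points)), function(q) {
    lam <- c(1 - sum(quad$points[q, ]), quad$points[q, ])
    x <- 0
    for (k in seq_len(d + 1L)) {
      x <- x + lam[k] * mesh$vertices[mesh$cells[, k], , drop = FALSE]
    }
    x
  })
}

#' L2 error of a finite-element field against a closed-form reference
#'
#' Integrates `|field - exact|^2` over the domain with a quadrature rule of
#' at least the requested degree and returns the square root.
#'
#' @param f an `fe_function` (scalar or vector coefficients).
#' @param exact function(x) returning the reference values.
#' @param degree quadrature degree; defaults to twice the field degree plus
#'   four (enough for the polynomial benchmarks here).
#' @return nonnegative scalar.
#' @export
l2_error <- function(f, exact, degree = NULL) {
  sp <- f$space
  if (is.null(degree)) degree <- 2L * sp$degree + 4L
  quad <- simplex_quadrature(sp$dim, degree)
  geo <- cell_geometry(sp$mesh)
  ev <- eval_on_cells(f, quad, geo)
  xs <- vol_qpoints(sp$mesh, quad)
  acc <- 0
  for (q in seq_along(xs)) {
    diff <- ev$vals[[q]] - as.matrix(exact(xs[[q]]))
    acc <- acc + quad$weights[q] * sum(geo$detJ * rowSums(diff^2))
  }
  sqrt(max(acc, 0))
}

# L2 norm of the divergence of a vector fe_function
l2_div_norm <- function(f, degree = NULL) {
  sp <- f$space
  if (is.null(degree)) degree <- 2L * (sp$degree - 1L) + 2L
  quad <- simplex_quadrature(sp$dim, max(1L, degree))
  geo <- cell_geometry(sp$mesh)
  ev <- eval_on_cells(f, quad, geo, gradients = TRUE)
  acc <- 0
  for (q in seq_len(nrow(quad$points))) {
    divv <- 0
    for (a in seq_len(sp$dim)) divv <- divv + ev$grads[[q]][[a]][, a]
    acc <- acc + quad$weights[q] * sum(geo$detJ * divv^2)
  }
  sqrt(max(acc, 0))
}

#' Fit a log-log convergence rate
#'
#' Least-squares slope of `log(error)` against `log(h)`.
#'
#' @param resolutions mesh sizes h (positive, decreasing or not).
#' @param errors corresponding positive errors.
#' @return the fitted rate (positive for decaying errors).
#' @export
fit_convergence_rate <- function(resolutions, errors) {
  if (length(resolutions) != length(errors) || length(errors) < 2L) {
    stop("need at least two (resolution, error) pairs")
  }
  if (any(errors <= 0)) stop("errors must be positive for a log-log fit")
  if (any(resolutions <= 0)) stop("resolutions must be positive")
  unname(stats::coef(stats::lm(log(errors) ~ log(resolutions)))[2])
}
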
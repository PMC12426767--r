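# Hemodynamic indicators over a tagged aneurysm surface: dome WSS extrema
# and area-weighted average, and the low shear area (LSA) -- the percentage
# of the dome exposed to WSS below 10% of the parent-artery mean.

#' Hemodynamic summary of a WSS field over a tagged dome region
#'
#' The parent-artery mean WSS is the area-weighted mean of `|tau|` over the
#' parent region, computed with the same WSS field (hence the same recovery
#' method).  Max/min are taken over the method's native evaluation points
#' (facet nodes for P1/DG-1, facet values for DG-0); the average is the
#' area-weighted mean; LSA thresholds `|tau|` facet-quadrature-wise at 10% of
#' the parent mean.
#'
#' @param wss a `wss_field` covering both regions.
#' @param dome_tag,parent_tag region ids or labels (disjoint).
#' @param threshold_fraction LSA threshold as a fraction of the parent mean
#'   (default 0.1).
#' @return a `hemodynamic_summary` with max/min/avg WSS (Pa), `lsa` (%),
#'   `parent_mean` and `threshold`.
#' @export
hemodynamic_summary <- function(wss, dome_tag, parent_tag,
                                threshold_fraction = 0.1) {
  mesh <- wss$mesh
  dome <- resolve_tag(mesh, dome_tag)
  parent <- resolve_tag(mesh, parent_tag)
  if (dome == parent) stop("dome and parent regions must be disjoint")
  ftags <- mesh$facet_tags[wss$facet_sel]
  in_dome <- ftags == dome
  in_parent <- ftags == parent
  if (!any(in_dome)) stop("empty dome region")
  if (!any(in_parent)) stop("empty parent region")

  rule <- simplex_quadrature(mesh$dim - 1L, 2L * max(1L, wss$facet_degree))
  vals <- wss_at_qps(wss, rule)
  w <- as.vector(facet_qweights(mesh, wss$facet_sel, rule))
  mag <- sqrt(rowSums(vals^2))
  nq <- nrow(rule$points)
  dsel <- rep(in_dome, nq)
  psel <- rep(in_parent, nq)

  parent_mean <- sum(w[psel] * mag[psel]) / sum(w[psel])
  threshold <- threshold_fraction * parent_mean
  dome_area <- sum(w[dsel])
  avg <- sum(w[dsel] * mag[dsel]) / dome_area
  lsa <- 100 * sum(w[dsel] * (mag[dsel] < threshold)) / dome_area

  nodal_mag <- sqrt(apply(wss$facet_vals[in_dome, , , drop = FALSE]^2,
                          c(1, 2), sum))
  out <- list(region = mesh$region_names[[as.character(dome)]],
              max_wss = max(nodal_mag), min_wss = min(nodal_mag), avg_wss = avg,
              lsa = lsa, parent_mean_wss = parent_mean, threshold = threshold,
              dome_area = dome_area, method = wss$method, space = wss$space)
  tol <- 1e-12 * max(1, out$avg_wss)
  stopifnot(out$min_wss <= out$avg_wss + tol, out$avg_wss <= out$max_wss + tol)
  structure(out, class = "hemodynamic_summary")
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf("<hemodynamic_summary> %s (%s %s)\n", x$region, x$method, x$space))
  cat(sprintf("  WSS max/avg/min: %.4g / %.4g / %.4g Pa\n",
              x$max_wss, x$avg_wss, x$min_wss))
  cat(sprintf("  parent mean %.4g Pa, threshold %.4g Pa, LSA %.2f%%\n",
              x$parent_mean_wss, x$threshold, x$lsa))
  invisible(x)
}
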
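# Wall-shear-stress recovery from a flow solution: L2 projection of the
# tangential traction onto P1/DG-1/DG-0 boundary spaces, and the
# variationally consistent boundary-flux evaluation in P1 or P2, including
# the Nitsche-consistent variant and per-segment corner handling.

#' Tangential part of a vector with respect to a unit normal
#'
#' @param a numeric vector or matrix (rows = vectors).
#' @param n unit normal vector or matrix of matching shape.
#' @return `a - (a . n) n`, orthogonal to `n`.
#' @export
tangential_part <- function(a, n) {
  a <- rbind(a); n <- rbind(n)
  if (nrow(n) == 1L && nrow(a) > 1L) n <- n[rep(1L, nrow(a)), , drop = FALSE]
  an <- rowSums(a * n)
  out <- a - an * n
  if (nrow(out) == 1L) drop(out) else out
}

# facet reference basis (dimension dim-1), degree 0/1/2, nodes: vertices then
# edge midpoints (3D edge order (1,2), (2,3), (1,3) as in tri_edges)
facet_basis <- function(fdim, degree, pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (degree == 0L) return(matrix(1, 1, n))
  if (fdim == 1L) {
    t <- pts[, 1]
    if (degree == 1L) return(rbind(1 - t, t))
    rbind((1 - t) * (1 - 2 * t), t * (2 * t - 1), 4 * t * (1 - t))
  } else {
    ref_basis(2L, degree, pts)$val
  }
}

# construct a wss_field container
new_wss_field <- function(sol, method, space_name, facet_sel, facet_vals,
                          coefs = NULL, restriction = "whole_domain_interior_zero",
                          segments = NULL) {
  mesh <- sol$mesh
  structure(list(
    mesh = mesh, method = method, space = space_name,
    facet_sel = facet_sel,
    facet_degree = switch(space_name, DG0 = 0L, DG1 = 1L, P1 = 1L, P2 = 2L),
    facet_vals = facet_vals,       # array (nf, nnodes, dim)
    coefs = coefs,                 # global coefficients for continuous spaces
    restriction = restriction, segments = segments,
    tags = unique(mesh$facet_tags[facet_sel])
  ), class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  s <- wss_summary_stats(x)
  cat(sprintf("<wss_field> %s(%s) on %d facets: |tau| avg %.4g, range [%.4g, %.4g]\n",
              x$method, x$space, length(x$facet_sel), s$avg, s$min, s$max))
  invisible(x)
}

# evaluate a wss_field at facet quadrature points (stacked facet-major layout)
wss_at_qps <- function(wf, rule) {
  fdim <- wf$mesh$dim - 1L
  phi <- facet_basis(fdim, wf$facet_degree, rule$points)
  nf <- dim(wf$facet_vals)[1]
  nq <- nrow(rule$points)
  d <- wf$mesh$dim
  out <- matrix(0, nf * nq, d)
  for (a in seq_len(d)) {
    for (i in seq_len(nrow(phi))) {
      out[, a] <- out[, a] + rep(phi[i, ], each = nf) * wf$facet_vals[, i, a]
    }
  }
  out
}

# physical coordinates of facet quadrature points (same layout)
facet_qpoints <- function(mesh, facet_sel, rule) {
  f <- mesh$boundary_facets[facet_sel, , drop = FALSE]
  d <- mesh$dim
  nq <- nrow(rule$points)
  nf <- nrow(f)
  out <- matrix(0, nf * nq, d)
  for (q in seq_len(nq)) {
    if (d == 2L) {
      t <- rule$points[q, 1]
      x <- (1 - t) * mesh$vertices[f[, 1], , drop = FALSE] +
        t * mesh$vertices[f[, 2], , drop = FALSE]
    } else {
      s <- rule$points[q, 1]; t <- rule$points[q, 2]
      x <- (1 - s - t) * mesh$vertices[f[, 1], , drop = FALSE] +
        s * mesh$vertices[f[, 2], , drop = FALSE] +
        t * mesh$vertices[f[, 3], , drop = FALSE]
    }
    out[(q - 1L) * nf + seq_len(nf), ] <- x
  }
  out
}

# physical quadrature weights for the facets (nf x nq)
facet_qweights <- function(mesh, facet_sel, rule) {
  refmeas <- if (mesh$dim == 2L) 1 else 0.5
  outer(mesh$boundary_measure[facet_sel] / refmeas, rule$weights)
}

#' L2 projection of the tangential traction onto a boundary space
#'
#' Solves `int_wall tau . phi dS = int_wall (viscous traction)_t . phi dS`
#' for `tau` in the chosen space.  The pressure contribution is purely normal
#' and drops from the right-hand side.  DG spaces are solved facet-locally;
#' the continuous P1 system is assembled on the whole space with interior
#' rows replaced by identity (zero interior values).
#'
#' @param sol a `flow_solution`.
#' @param wall_tags tags (ids or labels) of the wall region(s).
#' @param space "P1", "DG1" or "DG0".
#' @param restriction "whole_domain_interior_zero" or "boundary_only"
#'   (identical values on the wall; kept for the record).
#' @return a `wss_field`.
#' @export
project_wss <- function(sol, wall_tags, space = c("P1", "DG1", "DG0"),
                        restriction = "whole_domain_interior_zero") {
  space <- match.arg(space)
  mesh <- sol$mesh
  d <- mesh$dim
  tags <- resolve_tags(mesh, wall_tags)
  facet_sel <- which(mesh$facet_tags %in% tags)
  if (!length(facet_sel)) stop("empty wall: no facets carry the given tags")
  qdeg <- sol$qdeg_facet
  fe <- boundary_field_eval(sol, facet_sel, qdeg, sol$geo)
  nq <- fe$bbv$nq; nf <- fe$bbv$nf
  nrm <- rep_facet(fe$bbv$normal, nq)
  # viscous traction, tangential part (pointwise identical to tangential Tn)
  tv <- traction_at(list(v = fe$v, grad = fe$grad, p = 0 * fe$p), nrm,
                    sol$props$nu, sol$config$stress_form)
  tt <- tv - rowSums(tv * nrm) * nrm
  w <- as.vector(facet_qweights(mesh, facet_sel, simplex_quadrature(d - 1L, qdeg)))
  rule <- simplex_quadrature(d - 1L, qdeg)
  if (space == "P1") {
    proj_continuous(sol, facet_sel, tt, w, rule, restriction)
  } else {
    proj_dg(sol, facet_sel, tt, w, rule, space, restriction)
  }
}

# continuous P1 projection on the wall trace
proj_continuous <- function(sol, facet_sel, tt, w, rule, restriction) {
  mesh <- sol$mesh
  d <- mesh$dim
  sp <- sol$space_p          # P1 scalar space shares the vertex dof map
  bb <- boundary_basis_points(sp, facet_sel, rule, sol$geo)
  nf <- bb$nf; nq <- bb$nq
  qsum <- function(x) rowSums(matrix(x, nf, nq))
  tr <- trip_new()
  rhs <- matrix(0, sp$ndof, d)
  for (i in seq_len(bb$nb)) {
    for (j in seq_len(bb$nb)) {
      tr <- trip_add(tr, bb$dofs[, i], bb$dofs[, j],
                     qsum(w * bb$val[i, ] * bb$val[j, ]))
    }
    for (a in seq_len(d)) {
      rhs[, a] <- rhs[, a] + vec_accumulate(bb$dofs[, i],
                                            qsum(w * bb$val[i, ] * tt[, a]),
                                            sp$ndof)
    }
  }
  M <- trip_mat(tr, sp$ndof, sp$ndof)
  wall_dofs <- sort(unique(as.vector(
    mesh$boundary_facets[facet_sel, , drop = FALSE])))
  coefs <- solve_restricted(M, rhs, wall_dofs)
  fvals <- gather_facet_vals(sol, facet_sel, coefs, 1L)
  new_wss_field(sol, "projection", "P1", facet_sel, fvals, coefs, restriction)
}

# facet-local DG projections
proj_dg <- function(sol, facet_sel, tt, w, rule, space, restriction) {
  mesh <- sol$mesh
  d <- mesh$dim
  fdim <- d - 1L
  deg <- if (space == "DG0") 0L else 1L
  phi <- facet_basis(fdim, deg, rule$points)
  nn <- nrow(phi)
  nf <- length(facet_sel); nq <- nrow(rule$points)
  wmat <- matrix(w, nf, nq)
  # local mass matrices and loads
  Mloc <- array(0, c(nf, nn, nn))
  rloc <- array(0, c(nf, nn, d))
  for (i in seq_len(nn)) {
    for (j in seq_len(nn)) {
      Mloc[, i, j] <- rowSums(wmat * matrix(rep(phi[i, ], each = nf) *
                                              rep(phi[j, ], each = nf), nf, nq))
    }
    for (a in seq_len(d)) {
      rloc[, i, a] <- rowSums(matrix(w * rep(phi[i, ], each = nf) * tt[, a],
                                     nf, nq))
    }
  }
  fvals <- array(0, c(nf, nn, d))
  if (nn == 1L) {
    for (a in seq_len(d)) fvals[, 1, a] <- rloc[, 1, a] / Mloc[, 1, 1]
  } else {
    for (f in seq_len(nf)) {
      fvals[f, , ] <- solve(Mloc[f, , ], rloc[f, , ])
    }
  }
  new_wss_field(sol, "projection", space, facet_sel, fvals, NULL, restriction)
}

# replace identity rows for dofs not in `keep`, then solve (possibly multiple
# right-hand sides); returns the full coefficient matrix
solve_restricted <- function(M, rhs, keep) {
  n <- nrow(M)
  rhs <- as.matrix(rhs)
  mask <- rep(1, n); mask[keep] <- 0
  D <- Matrix::Diagonal(n, 1 - mask)
  Mr <- D %*% M %*% D + Matrix::Diagonal(n, mask)
  rhs[-keep, ] <- 0
  out <- matrix(0, n, ncol(rhs))
  solm <- sparse_solve(methods::as(Mr, "CsparseMatrix"), rhs)
  as.matrix(solm)
}

# nodal values of a continuous field gathered per facet
gather_facet_vals <- function(sol, facet_sel, coefs, deg) {
  mesh <- sol$mesh
  d <- mesh$dim
  f <- mesh$boundary_facets[facet_sel, , drop = FALSE]
  sp <- if (deg == 1L) sol$space_p else sol$space_v  # vertex map vs P2 map
  fd <- facet_scalar_dofs(sp, f)
  nn <- ncol(fd)
  nf <- nrow(f)
  out <- array(0, c(nf, nn, d))
  for (a in seq_len(d)) out[, , a] <- matrix(coefs[fd, a], nf, nn)
  out
}

#' Variationally consistent boundary-flux evaluation of WSS
#'
#' Recovers the wall traction by testing the discrete momentum residual with
#' boundary-supported functions: volume stress and force terms, the
#' stabilization tested with `(phi, 0)`, subtraction of the discrete normal
#' traction on the wall and of the full discrete traction on the remaining
#' boundary segments, plus the two retained Nitsche terms (consistency
#' transpose and penalty) on every Nitsche-enforced Dirichlet region when the
#' solution was obtained that way.  For steady Navier-Stokes solutions the
#' convection (and final BDF2 time-derivative) terms are included.
#'
#' @param sol a `flow_solution`.
#' @param wall_tags wall region tag(s) where WSS is recovered.
#' @param space "P1" or "P2" (P2 requires a P2 velocity solution).
#' @param neumann_tags regions whose discrete traction is subtracted
#'   (default: all non-wall regions).
#' @return a `wss_field`.
#' @export
boundary_flux_wss <- function(sol, wall_tags, space = c("P1", "P2"),
                              neumann_tags = NULL) {
  space <- match.arg(space)
  mesh <- sol$mesh
  d <- mesh$dim
  degw <- if (space == "P1") 1L else 2L
  if (degw > sol$space_v$degree) {
    stop("boundary-flux space exceeds the velocity degree of the solution")
  }
  tags <- resolve_tags(mesh, wall_tags)
  wall_sel <- which(mesh$facet_tags %in% tags)
  if (!length(wall_sel)) stop("empty wall: no facets carry the given tags")
  other_tags <- if (is.null(neumann_tags)) {
    setdiff(unique(mesh$facet_tags), tags)
  } else resolve_tags(mesh, neumann_tags)
  ov <- mesh$facet_tags %in% other_tags
  if (any(!(mesh$facet_tags %in% c(tags, other_tags)))) {
    stop("wall and neumann tags do not partition the boundary")
  }
  spw <- if (degw == sol$space_v$degree) sol$space_v else sol$space_p
  if (spw$degree != degw) spw <- fe_space(mesh, degw)

  rhs <- bflux_volume_residual(sol, spw)
  rhs <- rhs + bflux_stabilization(sol, spw)
  qrule <- simplex_quadrature(d - 1L, sol$qdeg_facet)
  # wall: subtract normal traction
  rhs <- rhs + bflux_boundary_term(sol, spw, wall_sel, qrule, "normal_only")
  # other segments: subtract full traction
  other_sel <- which(ov)
  if (length(other_sel)) {
    rhs <- rhs + bflux_boundary_term(sol, spw, other_sel, qrule, "full")
  }
  rhs <- rhs + bflux_nitsche_retained(sol, spw, qrule)

  # wall mass matrix on the test space
  bb <- boundary_basis_points(spw, wall_sel, qrule, sol$geo)
  w <- as.vector(facet_qweights(mesh, wall_sel, qrule))
  nf <- bb$nf; nq <- bb$nq
  qsum <- function(x) rowSums(matrix(x, nf, nq))
  tr <- trip_new()
  for (i in seq_len(bb$nb)) for (j in seq_len(bb$nb)) {
    tr <- trip_add(tr, bb$dofs[, i], bb$dofs[, j],
                   qsum(w * bb$val[i, ] * bb$val[j, ]))
  }
  M <- trip_mat(tr, spw$ndof, spw$ndof)
  wall_dofs <- boundary_scalar_dofs(spw, tags)
  rhsm <- matrix(rhs, ncol = d, byrow = TRUE)
  coefs <- solve_restricted(M, rhsm, wall_dofs)
  fvals <- gather_facet_vals_space(spw, wall_sel, coefs)
  new_wss_field(sol, "boundary_flux", space, wall_sel, fvals, coefs)
}

gather_facet_vals_space <- function(spw, facet_sel, coefs) {
  mesh <- spw$mesh
  d <- mesh$dim
  f <- mesh$boundary_facets[facet_sel, , drop = FALSE]
  fd <- facet_scalar_dofs(spw, f)
  nn <- ncol(fd)
  out <- array(0, c(nrow(f), nn, d))
  for (a in seq_len(d)) out[, , a] <- matrix(coefs[fd, a], nrow(f), nn)
  out
}

# volume residual terms: int T : grad(phi e_a) - f . phi (+ NS terms)
bflux_volume_residual <- function(sol, spw) {
  mesh <- sol$mesh
  d <- mesh$dim
  nu <- sol$props$nu
  degq <- 2L * sol$space_v$degree + 1L
  quad <- simplex_quadrature(d, degq)
  geo <- sol$geo
  fv <- fe_function(sol$space_v, sol$v)
  ev <- eval_on_cells(fv, quad, geo, gradients = TRUE)
  fp <- fe_function(sol$space_p, sol$p)
  ep <- eval_on_cells(fp, quad, geo)
  rbw <- ref_basis(d, spw$degree, quad$points)
  xs <- if (!is.null(sol$bcs$f)) vol_qpoints(mesh, quad) else NULL
  is_ns <- identical(sol$problem, "navier_stokes")
  dudt <- if (is_ns && !is.null(sol$dudt)) {
    eval_on_cells(fe_function(sol$space_v, sol$dudt), quad, geo)
  } else NULL
  rho <- sol$props$rho
  rhs <- numeric(spw$ndof * d)
  for (q in seq_len(nrow(quad$points))) {
    wq <- quad$weights[q] * geo$detJ
    pg <- phys_grads_at(geo, rbw$grad[, , q, drop = TRUE], spw$nb, d)
    pvals <- ep$vals[[q]][, 1]
    conv <- NULL
    if (is_ns) {
      conv <- matrix(0, length(wq), d)
      for (a in seq_len(d)) {
        acc <- 0
        for (b in seq_len(d)) {
          acc <- acc + ev$grads[[q]][[a]][, b] * ev$vals[[q]][, b]
        }
        conv[, a] <- acc
        if (!is.null(dudt)) conv[, a] <- conv[, a] + dudt$vals[[q]][, a]
      }
    }
    fq <- if (!is.null(xs)) as.matrix(sol$bcs$f(xs[[q]])) else NULL
    for (i in seq_len(spw$nb)) {
      for (a in seq_len(d)) {
        integ <- -pvals * pg[[i]][, a]
        for (b in seq_len(d)) {
          gab <- ev$grads[[q]][[a]][, b]
          if (sol$config$stress_form == "symmetric") {
            gab <- gab + ev$grads[[q]][[b]][, a]
          }
          integ <- integ + nu * gab * pg[[i]][, b]
        }
        if (is_ns) integ <- integ + rho * conv[, a] * rbw$val[i, q]
        if (!is.null(fq)) integ <- integ - fq[, a] * rbw$val[i, q]
        rhs <- rhs + vec_accumulate(vdof(spw$cell_dofs[, i], a, d),
                                    integ * wq, spw$ndof * d)
      }
    }
  }
  rhs
}

# stabilization tested with (phi, 0): only velocity jump terms contribute
bflux_stabilization <- function(sol, spw) {
  d <- sol$mesh$dim
  rhs <- numeric(spw$ndof * d)
  st <- sol$stab
  if (is.null(st)) return(rhs)
  if (spw$degree != sol$space_v$degree) {
    # the stabilized pair is P1/P1; the test space then equals the solution
    # space, otherwise the stabilization of a P2 solution is void anyway
    return(rhs)
  }
  vvec <- as.numeric(t(sol$v))   # node-major interleaved
  if (st$style == "cip") {
    jump <- as.numeric(st$Gv %*% vvec)
    rhs <- rhs + as.numeric(Matrix::crossprod(st$Gv, st$Wv * jump))
  } else {
    # interior penalty: alpha_v and alpha_i terms, per component
    geoif <- st$ifg
    h2 <- geoif$h1^2 + geoif$h2^2
    wts <- sol$config$stabilization$alpha_v * h2 * geoif$measure
    if (!is.null(sol$ip_vn2)) {
      wts <- wts + sol$config$stabilization$alpha_i * h2 * sol$ip_vn2
    }
    for (b in seq_len(d)) {
      for (a in seq_len(d)) {
        ja <- as.numeric(st$Gb[[b]] %*% sol$v[, a])
        contrib <- as.numeric(Matrix::crossprod(st$Gb[[b]], wts * ja))
        idx <- vdof(seq_len(spw$ndof), a, d)
        rhs[idx] <- rhs[idx] + contrib
      }
    }
  }
  rhs
}

# - int (Tn . n)(n . phi)  (mode "normal_only") or - int Tn . phi ("full")
bflux_boundary_term <- function(sol, spw, facet_sel, qrule, mode) {
  mesh <- sol$mesh
  d <- mesh$dim
  fe <- boundary_field_eval_rule(sol, facet_sel, qrule)
  bbw <- boundary_basis_points(spw, facet_sel, qrule, sol$geo)
  nf <- bbw$nf; nq <- bbw$nq
  nrm <- rep_facet(bbw$normal, nq)
  tn <- traction_at(fe, nrm, sol$props$nu, sol$config$stress_form)
  w <- as.vector(facet_qweights(mesh, facet_sel, qrule))
  qsum <- function(x) rowSums(matrix(x, nf, nq))
  rhs <- numeric(spw$ndof * d)
  if (mode == "normal_only") {
    tnn <- rowSums(tn * nrm)
    for (i in seq_len(bbw$nb)) for (a in seq_len(d)) {
      rhs <- rhs - vec_accumulate(vdof(bbw$dofs[, i], a, d),
                                  qsum(w * tnn * nrm[, a] * bbw$val[i, ]),
                                  spw$ndof * d)
    }
  } else {
    for (i in seq_len(bbw$nb)) for (a in seq_len(d)) {
      rhs <- rhs - vec_accumulate(vdof(bbw$dofs[, i], a, d),
                                  qsum(w * tn[, a] * bbw$val[i, ]),
                                  spw$ndof * d)
    }
  }
  rhs
}

# retained Nitsche terms on every Nitsche-enforced Dirichlet region:
# + int (T(phi,0) n) . (v - v_bc) + beta nu / h int (v - v_bc) . phi
bflux_nitsche_retained <- function(sol, spw, qrule) {
  mesh <- sol$mesh
  d <- mesh$dim
  nu <- sol$props$nu
  rhs <- numeric(spw$ndof * d)
  if (sol$config$enforcement != "nitsche" || !length(sol$nitsche_facets)) {
    return(rhs)
  }
  beta <- sol$config$beta
  for (tag in names(sol$bcs$regions)) {
    r <- sol$bcs$regions[[tag]]
    if (r$kind != "dirichlet_nitsche") next
    fs <- which(mesh$facet_tags == resolve_tag(mesh, tag))
    fe <- boundary_field_eval_rule(sol, fs, qrule)
    bbw <- boundary_basis_points(spw, fs, qrule, sol$geo)
    nf <- bbw$nf; nq <- bbw$nq
    nrm <- rep_facet(bbw$normal, nq)
    hf <- rep.int(bbw$h, nq)
    vbcf <- if (is.null(r$value)) zero_fun(d) else r$value
    dv <- fe$v - as.matrix(vbcf(bbw$xq))
    w <- as.vector(facet_qweights(mesh, fs, qrule))
    qsum <- function(x) rowSums(matrix(x, nf, nq))
    for (i in seq_len(bbw$nb)) {
      gn_i <- 0
      for (b in seq_len(d)) gn_i <- gn_i + bbw$gphys[[i]][, b] * nrm[, b]
      for (a in seq_len(d)) {
        integ <- nu * gn_i * dv[, a] + beta * nu / hf * dv[, a] * bbw$val[i, ]
        if (sol$config$stress_form == "symmetric") {
          for (b in seq_len(d)) {
            integ <- integ + nu * bbw$gphys[[i]][, b] * nrm[, a] * dv[, b]
          }
        }
        rhs <- rhs + vec_accumulate(vdof(bbw$dofs[, i], a, d), qsum(w * integ),
                                    spw$ndof * d)
      }
    }
  }
  rhs
}

#' Compute a WSS field segment by segment
#'
#' Applies a WSS evaluator separately on each tagged boundary segment and
#' combines the per-segment fields facet-wise (each facet keeps the values of
#' its own segment's solve; corners get one-sided values per segment).  For
#' continuous recovery spaces this avoids the corner coupling between
#' segments with different tangent planes; for facet-local DG spaces it is a
#' no-op relative to the global evaluation.
#'
#' @param sol a `flow_solution`.
#' @param segment_tags ordered tags of the boundary segments.
#' @param method "projection" or "boundary_flux".
#' @param space WSS space ("P1", "DG1", "DG0" for projection; "P1", "P2" for
#'   boundary flux).
#' @return a combined `wss_field` with per-segment fields in `$segments`.
#' @export
wss_per_segment <- function(sol, segment_tags,
                            method = c("projection", "boundary_flux"),
                            space = "P1") {
  method <- match.arg(method)
  if (method == "boundary_flux") {
    return(boundary_flux_wss_per_segment(sol, segment_tags, space))
  }
  mesh <- sol$mesh
  tags <- resolve_tags(mesh, segment_tags)
  if (anyDuplicated(tags)) stop("overlapping segment tags")
  if (length(tags) == 1L) return(project_wss(sol, tags, space))
  fields <- lapply(tags, function(tg) project_wss(sol, tg, space))
  names(fields) <- as.character(tags)
  facet_sel <- which(mesh$facet_tags %in% tags)
  nn <- dim(fields[[1]]$facet_vals)[2]
  d <- mesh$dim
  fvals <- array(0, c(length(facet_sel), nn, d))
  for (k in seq_along(tags)) {
    sel_k <- mesh$facet_tags[facet_sel] == tags[k]
    fvals[sel_k, , ] <- fields[[k]]$facet_vals
  }
  new_wss_field(sol, "projection", fields[[1]]$space, facet_sel, fvals, NULL,
                segments = fields)
}

#' Boundary-flux WSS computed per boundary segment
#'
#' Boundary fluxes lose accuracy at corners where segments meet; computing
#' the flux separately on each segment (subtracting the discrete traction on
#' the other segments as Neumann data) restores the interior rate.  The
#' combined field takes each facet's values from its own segment's solve; at
#' shared corners each segment keeps its own one-sided value.
#'
#' @param sol a `flow_solution`.
#' @param segment_tags ordered tags of the boundary segments.
#' @param space "P1" or "P2".
#' @return a `wss_field` whose `segments` attribute holds the per-segment fields.
#' @export
boundary_flux_wss_per_segment <- function(sol, segment_tags,
                                          space = c("P1", "P2")) {
  space <- match.arg(space)
  mesh <- sol$mesh
  tags <- resolve_tags(mesh, segment_tags)
  if (anyDuplicated(tags)) stop("overlapping segment tags")
  if (length(tags) == 1L) {
    return(boundary_flux_wss(sol, tags, space))
  }
  fields <- lapply(tags, function(tg) boundary_flux_wss(sol, tg, space))
  names(fields) <- as.character(tags)
  facet_sel <- which(mesh$facet_tags %in% tags)
  nn <- dim(fields[[1]]$facet_vals)[2]
  d <- mesh$dim
  fvals <- array(0, c(length(facet_sel), nn, d))
  for (k in seq_along(tags)) {
    sel_k <- mesh$facet_tags[facet_sel] == tags[k]
    fvals[sel_k, , ] <- fields[[k]]$facet_vals
  }
  wf <- new_wss_field(sol, "boundary_flux", space, facet_sel, fvals,
                      NULL, segments = fields)
  wf
}

# ---- wss metrics ----------------------------------------------------------

#' L2 error of a WSS field against a closed-form reference
#'
#' Integrates `|tau_h - tau_exact|^2` over the field's facets.  The reference
#' is a function `exact(x, region_label)` so that per-segment closed forms
#' (e.g. a different trace on each side of the square) can be supplied.
#'
#' @param wf a `wss_field`.
#' @param exact function(x, region_label) -> matrix.
#' @param degree facet quadrature degree (default: field degree + 3).
#' @export
l2_error_wss <- function(wf, exact, degree = NULL) {
  mesh <- wf$mesh
  if (is.null(degree)) degree <- 2L * max(1L, wf$facet_degree) + 2L
  rule <- simplex_quadrature(mesh$dim - 1L, degree)
  vals <- wss_at_qps(wf, rule)
  xq <- facet_qpoints(mesh, wf$facet_sel, rule)
  w <- as.vector(facet_qweights(mesh, wf$facet_sel, rule))
  labs <- mesh$region_names[as.character(mesh$facet_tags[wf$facet_sel])]
  nq <- nrow(rule$points)
  labrep <- rep.int(labs, nq)
  err2 <- 0
  for (lb in unique(labs)) {
    sel <- labrep == lb
    diff <- vals[sel, , drop = FALSE] - as.matrix(exact(xq[sel, , drop = FALSE], lb))
    err2 <- err2 + sum(w[sel] * rowSums(diff^2))
  }
  sqrt(max(err2, 0))
}

# ratio of normal-component to total L2 energy, facet-wise normals
wss_tangentiality <- function(wf, degree = 4L) {
  mesh <- wf$mesh
  rule <- simplex_quadrature(mesh$dim - 1L, degree)
  vals <- wss_at_qps(wf, rule)
  nq <- nrow(rule$points)
  nrm <- rep_facet(mesh$boundary_normal[wf$facet_sel, , drop = FALSE], nq)
  w <- as.vector(facet_qweights(mesh, wf$facet_sel, rule))
  num <- sum(w * rowSums(vals * nrm)^2)
  den <- sum(w * rowSums(vals^2))
  if (den == 0) 0 else num / den
}

# area-weighted average and native-point extrema of |tau|
wss_summary_stats <- function(wf, degree = 4L) {
  mesh <- wf$mesh
  rule <- simplex_quadrature(mesh$dim - 1L, degree)
  vals <- wss_at_qps(wf, rule)
  w <- as.vector(facet_qweights(mesh, wf$facet_sel, rule))
  mag_q <- sqrt(rowSums(vals^2))
  area <- sum(w)
  nodal_mag <- sqrt(apply(wf$facet_vals^2, c(1, 2), sum))
  list(avg = sum(w * mag_q) / area,
       min = min(nodal_mag), max = max(nodal_mag), area = area)
}

# L2 distance between two wss fields over the same facets
wss_l2_distance <- function(wf1, wf2, degree = 5L) {
  stopifnot(identical(wf1$facet_sel, wf2$facet_sel))
  rule <- simplex_quadrature(wf1$mesh$dim - 1L, degree)
  v1 <- wss_at_qps(wf1, rule)
  v2 <- wss_at_qps(wf2, rule)
  w <- as.vector(facet_qweights(wf1$mesh, wf1$facet_sel, rule))
  sqrt(sum(w * rowSums((v1 - v2)^2)))
}
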
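# Sparse finite-element assembly: volume blocks of the Stokes/Navier-Stokes
# saddle-point system, non-symmetric Nitsche boundary terms, CIP and
# interior-penalty stabilization built from facet jump operators, and the
# boundary/volume residual evaluations used by the boundary-flux WSS method.

trip_new <- function() list(i = list(), j = list(), x = list())
trip_add <- function(tr, i, j, x) {
  k <- length(tr$i) + 1L
  tr$i[[k]] <- i; tr$j[[k]] <- j; tr$x[[k]] <- x
  tr
}
trip_mat <- function(tr, nrow, ncol) {
  Matrix::sparseMatrix(i = unlist(tr$i), j = unlist(tr$j), x = unlist(tr$x),
                       dims = c(nrow, ncol))
}

# ---- volume matrices ------------------------------------------------------

# stiffness: int coef * grad(phi_i) . grad(phi_j)
assemble_scalar_stiffness <- function(space, geo, coef = 1) {
  d <- space$dim; nb <- space$nb
  quad <- simplex_quadrature(d, max(1L, 2L * (space$degree - 1L)))
  rb <- ref_basis(d, space$degree, quad$points)
  nc <- nrow(space$cell_dofs)
  tr <- trip_new()
  for (q in seq_len(nrow(quad$points))) {
    pg <- phys_grads_at(geo, rb$grad[, , q, drop = TRUE], nb, d)
    wq <- quad$weights[q] * geo$detJ * coef
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      val <- rowSums(pg[[i]] * pg[[j]]) * wq
      tr <- trip_add(tr, space$cell_dofs[, i], space$cell_dofs[, j], val)
    }
  }
  trip_mat(tr, space$ndof, space$ndof)
}

# int coef * d_b phi_i * d_a phi_j  (cross-gradient block, symmetric stress)
assemble_grad_cross <- function(space, geo, a, b, coef = 1) {
  d <- space$dim; nb <- space$nb
  quad <- simplex_quadrature(d, max(1L, 2L * (space$degree - 1L)))
  rb <- ref_basis(d, space$degree, quad$points)
  tr <- trip_new()
  for (q in seq_len(nrow(quad$points))) {
    pg <- phys_grads_at(geo, rb$grad[, , q, drop = TRUE], nb, d)
    wq <- quad$weights[q] * geo$detJ * coef
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      tr <- trip_add(tr, space$cell_dofs[, i], space$cell_dofs[, j],
                     pg[[i]][, b] * pg[[j]][, a] * wq)
    }
  }
  trip_mat(tr, space$ndof, space$ndof)
}

# divergence coupling: list over components a of  int psi_i d_a phi_j
# (rows: pressure space, cols: scalar velocity space)
assemble_div <- function(space_v, space_p, geo) {
  d <- space_v$dim
  deg <- max(1L, space_v$degree - 1L + space_p$degree)
  quad <- simplex_quadrature(d, deg)
  rbv <- ref_basis(d, space_v$degree, quad$points)
  rbp <- ref_basis(d, space_p$degree, quad$points)
  out <- vector("list", d)
  for (a in seq_len(d)) {
    tr <- trip_new()
    for (q in seq_len(nrow(quad$points))) {
      pg <- phys_grads_at(geo, rbv$grad[, , q, drop = TRUE], space_v$nb, d)
      wq <- quad$weights[q] * geo$detJ
      for (i in seq_len(space_p$nb)) for (j in seq_len(space_v$nb)) {
        tr <- trip_add(tr, space_p$cell_dofs[, i], space_v$cell_dofs[, j],
                       rbp$val[i, q] * pg[[j]][, a] * wq)
      }
    }
    out[[a]] <- trip_mat(tr, space_p$ndof, space_v$ndof)
  }
  out
}

# scalar mass matrix
assemble_scalar_mass <- function(space, geo) {
  d <- space$dim
  quad <- simplex_quadrature(d, 2L * space$degree)
  rb <- ref_basis(d, space$degree, quad$points)
  nb <- space$nb
  tr <- trip_new()
  for (q in seq_len(nrow(quad$points))) {
    wq <- quad$weights[q] * geo$detJ
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      tr <- trip_add(tr, space$cell_dofs[, i], space$cell_dofs[, j],
                     rb$val[i, q] * rb$val[j, q] * wq)
    }
  }
  trip_mat(tr, space$ndof, space$ndof)
}

# int psi_i dx (pressure gauge vector)
assemble_unit_load <- function(space, geo) {
  d <- space$dim
  quad <- simplex_quadrature(d, space$degree)
  rb <- ref_basis(d, space$degree, quad$points)
  out <- numeric(space$ndof)
  for (q in seq_len(nrow(quad$points))) {
    wq <- quad$weights[q] * geo$detJ
    for (i in seq_len(space$nb)) {
      out <- out + vec_accumulate(space$cell_dofs[, i], rb$val[i, q] * wq,
                                  space$ndof)
    }
  }
  out
}

# sum duplicate-index contributions into a dense vector
vec_accumulate <- function(idx, vals, n) {
  out <- numeric(n)
  tab <- rowsum(vals, idx)
  out[as.integer(rownames(tab))] <- tab[, 1]
  out
}

# source term: int f . (phi_i e_a), f = function(x) -> matrix
assemble_source <- function(space, geo, f, degree = NULL) {
  d <- space$dim
  if (is.null(degree)) degree <- space$degree + 2L
  quad <- simplex_quadrature(d, degree)
  rb <- ref_basis(d, space$degree, quad$points)
  nc <- nrow(space$cell_dofs)
  rhs <- numeric(space$ndof * d)
  for (q in seq_len(nrow(quad$points))) {
    lam <- c(1 - sum(quad$points[q, ]), quad$points[q, ])
    xq <- 0
    for (k in seq_len(d + 1L)) {
      xq <- xq + lam[k] * space$mesh$vertices[space$mesh$cells[, k], , drop = FALSE]
    }
    fv <- as.matrix(f(xq))
    wq <- quad$weights[q] * geo$detJ
    for (i in seq_len(space$nb)) for (a in seq_len(d)) {
      rhs <- rhs + vec_accumulate(vdof(space$cell_dofs[, i], a, d),
                                  fv[, a] * rb$val[i, q] * wq, space$ndof * d)
    }
  }
  rhs
}

# ---- interior facet jump operators ---------------------------------------

# geometry of interior facets: measure, normal (from side 1), adjacent h_K
interior_facet_geometry <- function(mesh) {
  f <- mesh$interior_facets
  d <- mesh$dim
  p1 <- mesh$vertices[f[, 1], , drop = FALSE]
  p2 <- mesh$vertices[f[, 2], , drop = FALSE]
  if (d == 2L) {
    t <- p2 - p1
    len <- sqrt(rowSums(t^2))
    normal <- cbind(t[, 2], -t[, 1]) / len
    measure <- len
  } else {
    p3 <- mesh$vertices[f[, 3], , drop = FALSE]
    e1 <- p2 - p1; e2 <- p3 - p1
    cr <- cross3(e1, e2)
    nrm <- sqrt(rowSums(cr^2))
    normal <- cr / nrm
    measure <- nrm / 2
  }
  list(measure = measure, normal = normal,
       h1 = mesh$cell_h[mesh$interior_cells[, 1]],
       h2 = mesh$cell_h[mesh$interior_cells[, 2]])
}

# P1-only: constant physical gradients per cell, (nc x nb x d) as list
p1_cell_grads <- function(space, geo) {
  d <- space$dim
  rb <- ref_basis(d, 1L, matrix(rep(1 / (d + 1), d), 1))
  phys_grads_at(geo, rb$grad[, , 1, drop = TRUE], d + 1L, d)
}

# Jump operator matrices over interior facets for a P1 space.
# type "ngradp": rows = facets, entries n . grad(phi) (jump across facet)
# type "div":    rows = facets, cols = vector dofs, entries jump of d_a phi
# type "gradb":  list over b of jump of d_b phi (scalar dofs)
facet_jump_matrix <- function(space, geo, ifg, type) {
  stopifnot(space$degree == 1L)
  mesh <- space$mesh
  d <- space$dim
  pg <- p1_cell_grads(space, geo)
  nf <- nrow(mesh$interior_facets)
  kc <- mesh$interior_cells
  mk <- function(entries_fun, ncols, dofmap) {
    tr <- trip_new()
    for (side in 1:2) {
      sgn <- if (side == 1) 1 else -1
      cells <- kc[, side]
      for (i in seq_len(d + 1L)) {
        e <- entries_fun(cells, i)
        if (is.list(e)) {
          for (a in seq_len(length(e))) {
            tr <- trip_add(tr, seq_len(nf),
                           dofmap(space$cell_dofs[cells, i], a), sgn * e[[a]])
          }
        } else {
          tr <- trip_add(tr, seq_len(nf), dofmap(space$cell_dofs[cells, i], 1L),
                         sgn * e)
        }
      }
    }
    trip_mat(tr, nf, ncols)
  }
  if (type == "ngradp") {
    mk(function(cells, i) rowSums(ifg$normal * pg[[i]][cells, , drop = FALSE]),
       space$ndof, function(s, a) s)
  } else if (type == "div") {
    mk(function(cells, i) lapply(seq_len(d), function(a) pg[[i]][cells, a]),
       space$ndof * d, function(s, a) vdof(s, a, d))
  } else if (type == "gradb") {
    lapply(seq_len(d), function(b) {
      mk(function(cells, i) pg[[i]][cells, b], space$ndof, function(s, a) s)
    })
  } else stop("unknown jump type")
}

# ---- boundary facet basis data -------------------------------------------

# Everything needed to integrate over a subset of boundary facets: physical
# quadrature weights, outward normals, adjacent-cell h, test/trial basis
# values and physical gradients at the facet quadrature points, and the
# physical point coordinates.  Points are stacked facet-major per q-block:
# row index (q-1)*nf + f.
boundary_basis <- function(space, facet_sel, qdeg, geo) {
  rule <- simplex_quadrature(space$mesh$dim - 1L, qdeg)
  boundary_basis_points(space, facet_sel, rule, geo)
}

boundary_basis_points <- function(space, facet_sel, rule, geo) {
  mesh <- space$mesh
  d <- mesh$dim
  f <- mesh$boundary_facets[facet_sel, , drop = FALSE]
  cells <- mesh$boundary_cell[facet_sel]
  nf <- nrow(f)
  nq <- nrow(rule$points)
  refmeas <- if (d == 2L) 1 else 0.5
  wfac <- mesh$boundary_measure[facet_sel] / refmeas
  xq <- matrix(0, nf * nq, d)
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
    xq[(q - 1L) * nf + seq_len(nf), ] <- x
  }
  # pull back to cell reference coordinates
  xi <- matrix(0, nf * nq, d)
  p0 <- geo$p0[cells, , drop = FALSE]
  for (q in seq_len(nq)) {
    rows <- (q - 1L) * nf + seq_len(nf)
    dx <- xq[rows, , drop = FALSE] - p0
    for (b in seq_len(d)) {
      acc <- 0
      for (a in seq_len(d)) acc <- acc + geo$Binv[[b]][[a]][cells] * dx[, a]
      xi[rows, b] <- acc
    }
  }
  rb <- ref_basis(d, space$degree, xi)
  nb <- space$nb
  # physical gradients per basis fn at all stacked points
  gphys <- vector("list", nb)
  for (i in seq_len(nb)) {
    g <- matrix(0, nf * nq, d)
    for (a in seq_len(d)) {
      acc <- 0
      for (b in seq_len(d)) {
        acc <- acc + geo$Binv[[b]][[a]][rep.int(cells, nq)] * rb$grad[i, b, ]
      }
      g[, a] <- acc
    }
    gphys[[i]] <- g
  }
  list(nf = nf, nq = nq, w = outer(wfac, rule$weights), # nf x nq physical wts
       normal = mesh$boundary_normal[facet_sel, , drop = FALSE],
       h = mesh$cell_h[cells],
       dofs = space$cell_dofs[cells, , drop = FALSE],
       val = rb$val, gphys = gphys, xq = xq, nb = nb,
       facet_sel = facet_sel)
}

# evaluate a solution's velocity (values+gradients) and pressure at the
# quadrature points of a boundary_basis-compatible layout
boundary_field_eval <- function(sol, facet_sel, qdeg, geo) {
  rule <- simplex_quadrature(sol$mesh$dim - 1L, qdeg)
  boundary_field_eval_rule(sol, facet_sel, rule, geo)
}

boundary_field_eval_rule <- function(sol, facet_sel, rule, geo = NULL) {
  if (is.null(geo)) geo <- sol$geo
  bbv <- boundary_basis_points(sol$space_v, facet_sel, rule, geo)
  bbp <- boundary_basis_points(sol$space_p, facet_sel, rule, geo)
  d <- sol$mesh$dim
  npts <- bbv$nf * bbv$nq
  vvals <- matrix(0, npts, d)
  vgrad <- array(0, c(npts, d, d))   # [pt, comp a, deriv b]
  for (a in seq_len(d)) {
    coefs <- sol$v[, a]
    for (i in seq_len(bbv$nb)) {
      ci <- coefs[bbv$dofs[, i]]
      ciq <- rep.int(ci, bbv$nq)
      vvals[, a] <- vvals[, a] + ciq * bbv$val[i, ]
      for (b in seq_len(d)) {
        vgrad[, a, b] <- vgrad[, a, b] + ciq * bbv$gphys[[i]][, b]
      }
    }
  }
  pvals <- numeric(npts)
  for (i in seq_len(bbp$nb)) {
    pvals <- pvals + rep.int(sol$p[bbp$dofs[, i]], bbp$nq) * bbp$val[i, ]
  }
  list(v = vvals, grad = vgrad, p = pvals, bbv = bbv, bbp = bbp)
}

# traction Tn at stacked boundary quadrature points from discrete fields
traction_at <- function(fe, normal_rep, nu, stress_form) {
  d <- ncol(fe$v)
  tn <- matrix(0, nrow(fe$v), d)
  for (a in seq_len(d)) {
    acc <- -fe$p * normal_rep[, a]
    for (b in seq_len(d)) {
      gab <- fe$grad[, a, b]
      if (stress_form == "symmetric") gab <- gab + fe$grad[, b, a]
      acc <- acc + nu * gab * normal_rep[, b]
    }
    tn[, a] <- acc
  }
  tn
}

# replicate per-facet rows for all quadrature points (stacked layout)
rep_facet <- function(m, nq) {
  if (is.matrix(m)) m[rep(seq_len(nrow(m)), nq), , drop = FALSE]
  else rep.int(m, nq)
}
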
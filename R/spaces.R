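# Scalar Lagrange spaces (P1/P2) over a tagged_mesh, their cell dof maps, and
# evaluation of finite-element functions at quadrature points.  Vector fields
# use node-major interleaving: the global dof of scalar dof s, component a
# (1..dim) is (s-1)*dim + a.

#' Scalar Lagrange finite-element space
#'
#' @param mesh a `tagged_mesh`.
#' @param degree 1 or 2.
#' @return an `fe_space`: cell dof map, total dof count, nodal coordinates.
#' @export
fe_space <- function(mesh, degree) {
  degree <- as.integer(degree)
  stopifnot(degree %in% c(1L, 2L))
  d <- mesh$dim
  nv <- nrow(mesh$vertices)
  if (degree == 1L) {
    cell_dofs <- mesh$cells
    nodes <- mesh$vertices
    edge_key <- NULL
    edge_dof0 <- nv
  } else {
    edges <- if (d == 2L) tri_edges else tet_edges
    ne_loc <- nrow(edges)
    pairs <- do.call(rbind, lapply(seq_len(ne_loc), function(e) {
      mesh$cells[, edges[e, ], drop = FALSE]
    }))
    key <- facet_keys(pairs, nv)
    uk <- unique(key)
    eid <- match(key, uk)
    cell_dofs <- cbind(mesh$cells,
                       nv + matrix(eid, nrow = nrow(mesh$cells)))
    # midpoint coordinates of the unique edges
    first <- match(uk, key)
    mids <- (mesh$vertices[pairs[first, 1], , drop = FALSE] +
             mesh$vertices[pairs[first, 2], , drop = FALSE]) / 2
    nodes <- rbind(mesh$vertices, mids)
    edge_key <- uk
    edge_dof0 <- nv
  }
  structure(list(mesh = mesh, degree = degree, dim = d,
                 cell_dofs = cell_dofs, ndof = nrow(nodes), nodes = nodes,
                 nv = nv, edge_key = edge_key, edge_dof0 = edge_dof0,
                 nb = n_basis(d, degree)),
            class = "fe_space")
}

# vector dof ids (node-major interleaving) for scalar dofs s and component a
vdof <- function(s, a, dim) (s - 1L) * dim + a

# affine geometry of every cell: inverse Jacobian entries and |det J|
cell_geometry <- function(mesh) {
  d <- mesh$dim
  p0 <- mesh$vertices[mesh$cells[, 1], , drop = FALSE]
  E <- lapply(seq_len(d), function(k) {
    mesh$vertices[mesh$cells[, k + 1L], , drop = FALSE] - p0
  })
  # J columns are E[[k]]; invert per cell
  if (d == 2L) {
    det <- E[[1]][, 1] * E[[2]][, 2] - E[[1]][, 2] * E[[2]][, 1]
    Binv <- list(
      list(E[[2]][, 2] / det, -E[[2]][, 1] / det),
      list(-E[[1]][, 2] / det, E[[1]][, 1] / det)
    )
  } else {
    c1 <- E[[1]]; c2 <- E[[2]]; c3 <- E[[3]]
    cr23 <- cross3(c2, c3); cr31 <- cross3(c3, c1); cr12 <- cross3(c1, c2)
    det <- rowSums(c1 * cr23)
    # inv(J) rows are cross products of columns / det
    Binv <- list(
      list(cr23[, 1] / det, cr23[, 2] / det, cr23[, 3] / det),
      list(cr31[, 1] / det, cr31[, 2] / det, cr31[, 3] / det),
      list(cr12[, 1] / det, cr12[, 2] / det, cr12[, 3] / det)
    )
  }
  list(p0 = p0, E = E, Binv = Binv, detJ = abs(det))
}

# Physical gradients of all reference basis functions at one reference point.
# Returns list over basis i of (nc x dim) matrices.
phys_grads_at <- function(geo, gref_pt, nb, d) {
  lapply(seq_len(nb), function(i) {
    out <- matrix(0, length(geo$detJ), d)
    for (a in seq_len(d)) {
      acc <- 0
      for (b in seq_len(d)) acc <- acc + geo$Binv[[b]][[a]] * gref_pt[i, b]
      out[, a] <- acc
    }
    out
  })
}

#' A finite-element function (scalar or vector coefficients)
#' @param space an `fe_space`.
#' @param coefs numeric matrix (ndof x ncomp) or vector.
#' @export
fe_function <- function(space, coefs) {
  coefs <- as.matrix(coefs)
  stopifnot(nrow(coefs) == space$ndof)
  structure(list(space = space, coefs = coefs), class = "fe_function")
}

# interpolate a function(x-matrix) -> matrix at the nodal points
interpolate_nodal <- function(space, fun) {
  vals <- fun(space$nodes)
  fe_function(space, as.matrix(vals))
}

# Evaluate an fe_function and its gradient at the points of a reference
# quadrature rule, on every cell.  Returns values as list over quadrature
# points of (nc x ncomp) matrices, and gradients as list[q][[comp]] of
# (nc x dim) matrices.
eval_on_cells <- function(f, quad, geo = NULL, gradients = FALSE) {
  sp <- f$space
  d <- sp$dim
  if (is.null(geo)) geo <- cell_geometry(sp$mesh)
  rb <- ref_basis(d, sp$degree, quad$points)
  nq <- nrow(quad$points)
  nb <- sp$nb
  nc <- nrow(sp$cell_dofs)
  ncomp <- ncol(f$coefs)
  cf <- lapply(seq_len(ncomp), function(a) {
    matrix(f$coefs[sp$cell_dofs, a], nc, nb)
  })
  vals <- vector("list", nq)
  grads <- if (gradients) vector("list", nq) else NULL
  for (q in seq_len(nq)) {
    V <- matrix(0, nc, ncomp)
    for (a in seq_len(ncomp)) {
      acc <- 0
      for (i in seq_len(nb)) acc <- acc + cf[[a]][, i] * rb$val[i, q]
      V[, a] <- acc
    }
    vals[[q]] <- V
    if (gradients) {
      pg <- phys_grads_at(geo, rb$grad[, , q, drop = TRUE], nb, d)
      G <- vector("list", ncomp)
      for (a in seq_len(ncomp)) {
        acc <- matrix(0, nc, d)
        for (i in seq_len(nb)) acc <- acc + cf[[a]][, i] * pg[[i]]
        G[[a]] <- acc
      }
      grads[[q]] <- G
    }
  }
  list(vals = vals, grads = grads, quad = quad, geo = geo)
}

# scalar dofs whose support touches the given boundary regions:
# facet vertices plus (P2) facet edge midpoints
boundary_scalar_dofs <- function(space, tags) {
  mesh <- space$mesh
  tags <- resolve_tags(mesh, tags)
  sel <- mesh$facet_tags %in% tags
  f <- mesh$boundary_facets[sel, , drop = FALSE]
  dofs <- unique(as.vector(f))
  if (space$degree == 2L) {
    d <- mesh$dim
    ep <- if (d == 2L) {
      f
    } else {
      rbind(f[, c(1, 2)], f[, c(1, 3)], f[, c(2, 3)])
    }
    key <- facet_keys(ep, space$nv)
    eid <- match(key, space$edge_key)
    dofs <- c(dofs, space$edge_dof0 + unique(eid))
  }
  sort(dofs)
}

# scalar dofs of one boundary facet row (vertices, then P2 edge dofs)
facet_scalar_dofs <- function(space, facets) {
  f <- facets
  if (space$degree == 1L) return(f)
  d <- space$dim
  # edge order matches tri_edges: (1,2), (2,3), (1,3)
  ep <- if (d == 2L) {
    list(f)
  } else {
    list(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
         f[, c(1, 3), drop = FALSE])
  }
  eids <- lapply(ep, function(pp) {
    space$edge_dof0 + match(facet_keys(pp, space$nv), space$edge_key)
  })
  cbind(f, do.call(cbind, eids))
}
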
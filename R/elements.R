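# Lagrange reference elements (P1/P2) on triangles and tetrahedra, plus
# piecewise-constant/linear facet elements used for DG wall-shear-stress
# spaces.  Reference simplices: triangle (0,0),(1,0),(0,1); tetrahedron
# (0,0,0),(1,0,0),(0,1,0),(0,0,1).

# local edges carrying the P2 mid-edge nodes, in the order the global dof map
# numbers them
tri_edges <- matrix(c(1L, 2L,  2L, 3L,  1L, 3L), ncol = 2, byrow = TRUE)
tet_edges <- matrix(c(1L, 2L,  1L, 3L,  1L, 4L,
                      2L, 3L,  2L, 4L,  3L, 4L), ncol = 2, byrow = TRUE)

# local facets: facet i is opposite vertex i
tri_facets <- matrix(c(2L, 3L,  1L, 3L,  1L, 2L), ncol = 2, byrow = TRUE)
tet_facets <- matrix(c(2L, 3L, 4L,  1L, 3L, 4L,  1L, 2L, 4L,  1L, 2L, 3L),
                     ncol = 3, byrow = TRUE)

#' Evaluate reference Lagrange basis functions
#'
#' @param dim 2 or 3.
#' @param degree 1 or 2.
#' @param pts matrix (n x dim) of reference coordinates.
#' @return list `val` (nb x n) and `grad` (nb x dim x n array) of basis values
#'   and reference gradients.
#' @keywords internal
ref_basis <- function(dim, degree, pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (dim == 2L) {
    l <- cbind(1 - pts[, 1] - pts[, 2], pts[, 1], pts[, 2])
    dl <- rbind(c(-1, -1), c(1, 0), c(0, 1))
    edges <- tri_edges
  } else {
    l <- cbind(1 - rowSums(pts), pts[, 1], pts[, 2], pts[, 3])
    dl <- rbind(c(-1, -1, -1), diag(3))
    edges <- tet_edges
  }
  nv <- dim + 1L
  if (degree == 1L) {
    val <- t(l)
    grad <- array(0, c(nv, dim, n))
    for (i in seq_len(nv)) for (d in seq_len(dim)) grad[i, d, ] <- dl[i, d]
    return(list(val = val, grad = grad))
  }
  ne <- nrow(edges)
  nb <- nv + ne
  val <- matrix(0, nb, n)
  grad <- array(0, c(nb, dim, n))
  for (i in seq_len(nv)) {
    val[i, ] <- l[, i] * (2 * l[, i] - 1)
    for (d in seq_len(dim)) grad[i, d, ] <- (4 * l[, i] - 1) * dl[i, d]
  }
  for (e in seq_len(ne)) {
    a <- edges[e, 1]; b <- edges[e, 2]
    val[nv + e, ] <- 4 * l[, a] * l[, b]
    for (d in seq_len(dim)) {
      grad[nv + e, d, ] <- 4 * (l[, a] * dl[b, d] + l[, b] * dl[a, d])
    }
  }
  list(val = val, grad = grad)
}

# reference nodes of the scalar Lagrange element (vertices then edges)
ref_nodes <- function(dim, degree) {
  verts <- if (dim == 2L) rbind(c(0, 0), c(1, 0), c(0, 1)) else
    rbind(c(0, 0, 0), diag(3))
  if (degree == 1L) return(verts)
  edges <- if (dim == 2L) tri_edges else tet_edges
  rbind(verts, (verts[edges[, 1], , drop = FALSE] +
                verts[edges[, 2], , drop = FALSE]) / 2)
}

# number of scalar basis functions per cell
n_basis <- function(dim, degree) {
  nv <- dim + 1L
  if (degree == 1L) nv else nv + if (dim == 2L) 3L else 6L
}
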